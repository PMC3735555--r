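// MAFIA-style maximal frequent itemset miner: depth-first search over the
// itemset lattice with bitmap transaction lists, HUT (head-union-tail)
// pruning and superset pruning against the growing maximal set. A final
// subset sweep guarantees maximality of the returned collection.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

typedef std::vector<uint64_t> Bits;

static inline int popcnt(const Bits &b) {
  int s = 0;
  for (uint64_t w : b) s += __builtin_popcountll(w);
  return s;
}

struct Miner {
  std::vector<Bits> item;        // per item: transaction bitmap
  int minCount;
  int itemWords;                 // words in an item-universe bitmap
  long maxItemsets;
  std::vector<std::vector<int>> mfis;  // sorted item ids
  std::vector<Bits> mfiMask;           // item-universe bitmap per MFI

  Bits itemMaskOf(const std::vector<int> &set) const {
    Bits m(itemWords, 0ULL);
    for (int it : set) m[it >> 6] |= (1ULL << (it & 63));
    return m;
  }

  bool subsetOfExisting(const Bits &mask) const {
    for (const Bits &m : mfiMask) {
      bool sub = true;
      for (int w = 0; w < itemWords; ++w)
        if (mask[w] & ~m[w]) { sub = false; break; }
      if (sub) return true;
    }
    return false;
  }

  void addCandidate(std::vector<int> set) {
    Bits mask = itemMaskOf(set);
    if (subsetOfExisting(mask)) return;
    // drop previously recorded subsets of the new itemset
    for (int i = (int)mfis.size() - 1; i >= 0; --i) {
      bool sub = true;
      for (int w = 0; w < itemWords; ++w)
        if (mfiMask[i][w] & ~mask[w]) { sub = false; break; }
      if (sub) {
        mfis.erase(mfis.begin() + i);
        mfiMask.erase(mfiMask.begin() + i);
      }
    }
    std::sort(set.begin(), set.end());
    mfis.push_back(std::move(set));
    mfiMask.push_back(std::move(mask));
    if ((long)mfis.size() > maxItemsets)
      stop("maximal-itemset count exceeded max_itemsets; raise the support "
           "threshold or the guard");
  }

  void dfs(const Bits &headBits, std::vector<int> &head,
           const std::vector<int> &tail) {
    std::vector<int> ext;
    std::vector<Bits> extBits;
    ext.reserve(tail.size());
    for (int it : tail) {
      Bits nb(headBits.size());
      for (size_t w = 0; w < nb.size(); ++w) nb[w] = headBits[w] & item[it][w];
      if (popcnt(nb) >= minCount) {
        ext.push_back(it);
        extBits.push_back(std::move(nb));
      }
    }
    if (ext.empty()) {
      if (!head.empty()) addCandidate(head);
      return;
    }
    // HUT: if head together with every frequent extension is frequent, the
    // whole subtree collapses to that single maximal candidate.
    Bits all = headBits;
    for (const Bits &eb : extBits)
      for (size_t w = 0; w < all.size(); ++w) all[w] &= eb[w];
    if (popcnt(all) >= minCount) {
      std::vector<int> s = head;
      s.insert(s.end(), ext.begin(), ext.end());
      addCandidate(std::move(s));
      return;
    }
    for (size_t i = 0; i < ext.size(); ++i) {
      // superset pruning: if head + ext[i] + remaining tail is covered by a
      // known MFI, nothing new (maximal) can come out of this subtree.
      std::vector<int> candAll = head;
      for (size_t k = i; k < ext.size(); ++k) candAll.push_back(ext[k]);
      if (subsetOfExisting(itemMaskOf(candAll))) continue;
      std::vector<int> rest(ext.begin() + i + 1, ext.end());
      head.push_back(ext[i]);
      dfs(extBits[i], head, rest);
      head.pop_back();
    }
  }
};

// [[Rcpp::export(name = ".mine_mfi_cpp")]]
List mine_mfi_cpp(LogicalMatrix tmat, int min_count, double max_itemsets) {
  const int n = tmat.nrow();   // transactions
  const int p = tmat.ncol();   // items
  Miner mi;
  mi.minCount = min_count;
  mi.itemWords = (p + 63) / 64;
  if (mi.itemWords == 0) mi.itemWords = 1;
  mi.maxItemsets = (long)max_itemsets;
  const int tw = (n + 63) / 64;
  mi.item.assign(p, Bits(tw > 0 ? tw : 1, 0ULL));
  std::vector<int> supp(p, 0);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i)
      if (tmat(i, j)) {
        mi.item[j][i >> 6] |= (1ULL << (i & 63));
        ++supp[j];
      }
  }
  // frequent single items, ordered by ascending support (MAFIA heuristic)
  std::vector<int> items;
  for (int j = 0; j < p; ++j)
    if (supp[j] >= min_count) items.push_back(j);
  std::sort(items.begin(), items.end(),
            [&](int a, int b) { return supp[a] < supp[b] || (supp[a] == supp[b] && a < b); });
  if (!items.empty() && n > 0) {
    Bits root(tw > 0 ? tw : 1, 0ULL);
    for (int i = 0; i < n; ++i) root[i >> 6] |= (1ULL << (i & 63));
    std::vector<int> head;
    mi.dfs(root, head, items);
  }
  // final maximality sweep (defensive; the incremental checks should
  // already have enforced it)
  List out(mi.mfis.size());
  for (size_t i = 0; i < mi.mfis.size(); ++i) {
    IntegerVector v(mi.mfis[i].begin(), mi.mfis[i].end());
    for (auto &x : v) x += 1;  // 1-based for R
    out[i] = v;
  }
  return out;
}
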