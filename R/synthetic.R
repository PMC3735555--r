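#' Generate an expression matrix with planted interval structure
#'
#' Produces ground-truth data exercising every pipeline stage without any
#' external dataset. Noise genes are identically distributed across classes
#' (`Normal(0, noise_sd)`, or scaled t with 3 df under `heavy_tail`).
#' Signature genes carry one of two structures:
#'
#' * `"shift"` — class-specific means separated by `effect_size * noise_sd`;
#'   class-conditional values are truncated Gaussians (`+/- 1.25` sd around
#'   the class mean), so each class occupies a bounded generating interval
#'   and, for `effect_size >= 2.5`, the classes are literally disjoint.
#' * `"band"` — mean-matched mirrored band pairs (two classes only). With
#'   `h = effect_size * noise_sd`, the first class draws 2/3 of its samples
#'   uniformly from the main band `(h, 3h)` and 1/3 from the balance band
#'   `(-5h, -3h)`; the second class uses the mirror image. Both classes have
#'   fold-change ~ 0 and cover every symmetric interval identically, so
#'   mean-based filters and the ternary mean +/- sd discretizer are blind to
#'   them while the bands are perfectly interval-separable.
#'
#' @param n_per_class Samples per class (default 40).
#' @param n_classes Number of classes (default 2; `"band"` requires 2).
#' @param n_signature Signature genes (default 20).
#' @param n_noise Noise genes (default 480).
#' @param structure `"shift"` or `"band"`.
#' @param effect_size Mean separation in sd units (shift) or band half-width
#'   in `noise_sd` units (band); default 3.
#' @param noise_sd Noise standard deviation (default 1).
#' @param seed Integer seed; fully determines the output.
#' @param heavy_tail Draw noise genes from a scaled t(3) instead of a
#'   Gaussian.
#' @return A list of class `synthetic_dataset`: `x` (the
#'   [expression_matrix()]), `signature_genes`, `intervals` (per class, per
#'   signature gene, a matrix of generating `lo`/`hi` bands) and `spec`
#'   (the generating parameters).
#' @export
synthesize_dataset <- function(n_per_class = 40L, n_classes = 2L,
                               n_signature = 20L, n_noise = 480L,
                               structure = c("shift", "band"),
                               effect_size = 3, noise_sd = 1, seed = 0L,
                               heavy_tail = FALSE) {
  structure <- match.arg(structure)
  for (v in c(n_per_class, n_classes, n_signature, n_noise))
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1L)
      ic_validation("all synthetic counts must be positive integers")
  if (n_classes < 2L) ic_validation("'n_classes' must be >= 2")
  if (noise_sd <= 0) ic_validation("'noise_sd' must be positive")
  if (effect_size < 0) ic_validation("'effect_size' must be >= 0")
  if (structure == "band" && n_classes != 2L)
    ic_validation("band structure is defined for exactly 2 classes")
  set.seed(as.integer(seed))
  n_per_class <- as.integer(n_per_class)
  n_classes <- as.integer(n_classes)
  classes <- sprintf("class%02d", seq_len(n_classes))
  n <- n_per_class * n_classes
  labels <- rep(classes, each = n_per_class)
  sids <- sprintf("s%03d", seq_len(n))
  names(labels) <- sids
  sig_genes <- sprintf("sig%03d", seq_len(n_signature))
  noise_genes <- sprintf("noise%04d", seq_len(n_noise))
  vals <- matrix(0, n_signature + n_noise, n,
                 dimnames = list(c(sig_genes, noise_genes), sids))
  intervals <- NULL
  if (structure == "shift") {
    trunc <- 1.25
    pl <- pnorm(-trunc); pu <- pnorm(trunc)
    mu <- (match(labels, classes) - 1L) * effect_size * noise_sd
    for (g in sig_genes) {
      u <- runif(n, pl, pu)
      vals[g, ] <- mu + noise_sd * qnorm(u)
    }
    intervals <- lapply(classes, function(cl) {
      m <- (match(cl, classes) - 1L) * effect_size * noise_sd
      band <- matrix(c(m - trunc * noise_sd, m + trunc * noise_sd),
                     1L, 2L, dimnames = list(NULL, c("lo", "hi")))
      stats::setNames(rep(list(band), n_signature), sig_genes)
    })
    names(intervals) <- classes
  } else {
    h <- effect_size * noise_sd
    n_main <- as.integer(round(2 * n_per_class / 3))
    bands <- list(
      list(main = c(h, 3 * h), bal = c(-5 * h, -3 * h)),   # class 1
      list(main = c(-3 * h, -h), bal = c(3 * h, 5 * h)))   # class 2 (mirror)
    # antithetic pairs around each band center keep the class means pinned
    # at the deterministic center average, so fold-change ~ 0 by construction
    band_draw <- function(n, b) {
      m <- n %/% 2L
      u <- runif(m, 0, (b[2L] - b[1L]) / 2)
      ctr <- mean(b)
      c(ctr - u, ctr + u, if (n %% 2L) runif(1L, b[1L], b[2L]))
    }
    for (g in sig_genes) {
      for (k in 1:2) {
        idx <- which(labels == classes[k])
        b <- bands[[k]]
        v <- c(band_draw(n_main, b$main),
               band_draw(n_per_class - n_main, b$bal))
        vals[g, idx] <- v[sample.int(n_per_class)]
      }
    }
    intervals <- lapply(1:2, function(k) {
      band <- rbind(bands[[k]]$main, bands[[k]]$bal)
      colnames(band) <- c("lo", "hi")
      stats::setNames(rep(list(band), n_signature), sig_genes)
    })
    names(intervals) <- classes
  }
  for (g in noise_genes) {
    vals[g, ] <- if (heavy_tail) noise_sd * rt(n, df = 3) else
      rnorm(n, 0, noise_sd)
  }
  list_out <- list(x = expression_matrix(vals, labels),
                   signature_genes = sig_genes,
                   intervals = intervals,
                   spec = list(n_per_class = n_per_class,
                               n_classes = n_classes,
                               n_signature = as.integer(n_signature),
                               n_noise = as.integer(n_noise),
                               structure = structure,
                               effect_size = effect_size,
                               noise_sd = noise_sd, seed = as.integer(seed),
                               heavy_tail = isTRUE(heavy_tail)))
  class(list_out) <- "synthetic_dataset"
  list_out
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<synthetic_dataset> %s; %d classes x %d samples; %d signature + %d noise genes (seed %d)\n",
              s$structure, s$n_classes, s$n_per_class, s$n_signature,
              s$n_noise, s$seed))
  invisible(x)
}
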