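#' Reads-per-million normalization with zero revision
#'
#' Scales a count to reads per million of its library total; a normalized
#' value of exactly zero is revised to 0.01 so that fold changes stay finite.
#'
#' @param count nonnegative count(s).
#' @param library_total total reads in the library (> 0).
#' @param zero_value replacement for exact zeros (default 0.01).
#' @return numeric vector of normalized expression values.
#' @export
normalize_rpm <- function(count, library_total, zero_value = 0.01) {
  if (any(count < 0)) stop("negative count")
  if (any(library_total <= 0)) stop("library total must be positive")
  x <- count * 1e6 / library_total
  x[x == 0] <- zero_value
  x
}

#' Low-expression filter across libraries
#'
#' A miRNA is dropped only when its normalized expression is below the
#' threshold in every library.
#'
#' @param normalized matrix or data.frame (rows = miRNAs, columns = libraries)
#'   of normalized values, or a numeric vector for a single miRNA.
#' @param threshold minimum normalized expression (default 1).
#' @return logical vector: TRUE = keep.
#' @export
low_expression_filter <- function(normalized, threshold = 1) {
  m <- as.matrix(normalized)
  if (is.vector(normalized)) m <- matrix(normalized, nrow = 1)
  apply(m, 1L, function(r) any(r >= threshold))
}

#' Log2 fold change of normalized expression
#'
#' @param norm_treatment,norm_control positive normalized values (zeros must
#'   already have been revised, see [normalize_rpm()]).
#' @return log2(treatment / control); antisymmetric under swapping.
#' @export
log2_fold_change <- function(norm_treatment, norm_control) {
  if (any(norm_treatment <= 0) || any(norm_control <= 0)) {
    stop("fold change requires positive normalized values")
  }
  log2(norm_treatment / norm_control)
}

check_count <- function(x, name) {
  if (any(x < 0) || any(x != round(x))) {
    stop(name, " must be a nonnegative integer count")
  }
}

#' Audic-Claverie point probability
#'
#' Probability of observing `y` reads for a tag in a library of `N2` total
#' reads given `x` reads in a library of `N1` total reads, under proportional
#' sampling of tag counts:
#' \deqn{p(y|x) = (N_2/N_1)^y \frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}}}
#' Evaluated in log-gamma space, so there is no factorial overflow for counts
#' into the millions. When `n1 == n2` and `x + y` is small the exact binomial
#' closed form \eqn{\binom{x+y}{y} / 2^{x+y+1}} is used, which is exact in
#' double arithmetic.
#'
#' @param x,y nonnegative integer counts (vectorized).
#' @param n1,n2 library totals (> 0).
#' @return probabilities in (0, 1].
#' @export
audic_claverie_p <- function(x, y, n1, n2) {
  check_count(x, "x"); check_count(y, "y")
  if (n1 <= 0 || n2 <= 0) stop("library totals must be positive")
  k <- pmax(length(x), length(y))
  x <- rep_len(x, k); y <- rep_len(y, k)
  if (n1 == n2) {
    small <- (x + y) <= 1000
    p <- numeric(k)
    p[small] <- choose(x[small] + y[small], y[small]) / 2^(x[small] + y[small] + 1)
    if (any(!small)) {
      p[!small] <- exp(lchoose(x[!small] + y[!small], y[!small]) -
                         (x[!small] + y[!small] + 1) * log(2))
    }
    return(p)
  }
  r <- n2 / n1
  exp(y * log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
        (x + y + 1) * log1p(r))
}

#' Cumulative tail probabilities of the Audic-Claverie statistic
#'
#' For an observed treatment count `y_obs` given control count `x`:
#' `C` sums `p(y|x)` over `y = 0 .. y_obs` (lower tail) and `D` over
#' `y = y_obs .. Inf` (upper tail, computed as `1 - C + p(y_obs|x)` since the
#' kernel is a normalized negative-binomial form). The two tails overlap at
#' the observed point, so `C + D = 1 + p(y_obs|x)`.
#'
#' @param x control count; `y_obs` observed treatment count (scalars).
#' @param n1,n2 control / treatment library totals.
#' @return named numeric vector `c(C = , D = )`.
#' @export
cumulative_tails <- function(x, y_obs, n1, n2) {
  check_count(x, "x"); check_count(y_obs, "y_obs")
  stopifnot(length(x) == 1L, length(y_obs) == 1L)
  p_obs <- audic_claverie_p(x, y_obs, n1, n2)
  mode_y <- n2 / n1 * (x + 1)  # mean of the kernel over y
  if (y_obs <= mode_y) {
    # small lower tail: sum it directly, infer the upper one
    C <- sum(audic_claverie_p(x, 0:y_obs, n1, n2))
    D <- 1 - C + p_obs
  } else {
    # small upper tail: sum upward until the remaining mass is negligible
    D <- 0
    y <- y_obs
    chunk <- 256L
    repeat {
      terms <- audic_claverie_p(x, y:(y + chunk - 1L), n1, n2)
      D <- D + sum(terms)
      y <- y + chunk
      # stop once the running term is negligible relative to the mass seen
      # (or has underflowed entirely, for extreme tails)
      if (terms[chunk] < max(1e-12 * max(D, p_obs), 1e-300)) break
    }
    C <- 1 - D + p_obs
  }
  c(C = min(max(C, 0), 1), D = min(max(D, 0), 1))
}

#' Direction call for one expression comparison
#'
#' @param fold_change log2 fold change (treatment vs control).
#' @param p reported significance value (the smaller tail).
#' @param p_threshold,fc_threshold defaults 0.01 and 1 (i.e. two-fold).
#' @return `"up"`, `"down"`, or `"unchanged"`.
#' @export
significance_call <- function(fold_change, p, p_threshold = 0.01,
                              fc_threshold = 1) {
  ifelse(p <= p_threshold & fold_change >= fc_threshold, "up",
         ifelse(p <= p_threshold & fold_change <= -fc_threshold, "down",
                "unchanged"))
}

#' Digital differential expression over a three-library design
#'
#' For each miRNA and each treatment library, computes reads-per-million
#' normalized values (zeros revised to 0.01), the log2 fold change versus the
#' control library, both Audic-Claverie cumulative tails, the reported
#' significance `p = min(C, D)` (the paper-style convention: both tails are
#' emitted, the smaller one is reported), and a direction call. miRNAs whose
#' normalized expression is below `low_threshold` in all libraries are
#' flagged `filtered` and not called. The p-value always uses the raw integer
#' counts; the zero revision only affects normalized values and fold changes.
#'
#' @param counts data.frame: an id column (first column or `mirna`) plus one
#'   raw count column per library.
#' @param totals named vector of library totals (clean reads per library).
#' @param control name of the control library (default `"SD8"`).
#' @param p_threshold,fc_threshold thresholds for [significance_call()].
#' @param low_threshold normalized-expression filter (default 1).
#' @param adjust p-adjustment method (`"none"`, default, or any
#'   `stats::p.adjust` method such as `"BH"`), applied per comparison.
#' @return data.frame with one row per miRNA x treatment library:
#'   `mirna`, `treatment`, `x`, `y`, `norm_control`, `norm_treatment`,
#'   `fold_change`, `C`, `D`, `p`, `filtered`, `call`.
#' @export
diff_expression <- function(counts, totals, control = "SD8",
                            p_threshold = 0.01, fc_threshold = 1,
                            low_threshold = 1, adjust = "none") {
  id_col <- if ("mirna" %in% names(counts)) "mirna" else names(counts)[1]
  libs <- intersect(names(totals), names(counts))
  if (!control %in% libs) {
    stop("control library '", control, "' not among count columns")
  }
  treatments <- setdiff(libs, control)
  norm <- vapply(libs, function(lib) {
    normalize_rpm(counts[[lib]], totals[[lib]])
  }, numeric(nrow(counts)))
  if (nrow(counts) == 1L) {
    norm <- matrix(norm, nrow = 1L, dimnames = list(NULL, libs))
  }
  keep <- low_expression_filter(norm, low_threshold)
  out <- do.call(rbind, lapply(treatments, function(trt) {
    x <- counts[[control]]
    y <- counts[[trt]]
    tails <- t(vapply(seq_along(x), function(i) {
      cumulative_tails(x[i], y[i], totals[[control]], totals[[trt]])
    }, numeric(2)))
    p <- pmin(tails[, "C"], tails[, "D"])
    if (adjust != "none") p <- stats::p.adjust(p, method = adjust)
    fc <- log2_fold_change(norm[, trt], norm[, control])
    data.frame(mirna = counts[[id_col]], treatment = trt,
               x = x, y = y,
               norm_control = norm[, control], norm_treatment = norm[, trt],
               fold_change = fc, C = tails[, "C"], D = tails[, "D"], p = p,
               filtered = !keep,
               call = ifelse(keep,
                             significance_call(fc, p, p_threshold,
                                               fc_threshold),
                             "filtered"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Relative qPCR quantification (delta-delta-Ct)
#'
#' Computes `2^-((Ct_target - Ct_reference) - (Ct_target_cal -
#' Ct_reference_cal))`, the standard relative quantity of a target normalized
#' to an endogenous reference and a calibrator sample.
#'
#' @param ct_target,ct_reference Ct values in the sample of interest.
#' @param ct_target_cal,ct_reference_cal Ct values in the calibrator sample.
#' @return relative expression quantity.
#' @export
ddct_relative_expression <- function(ct_target, ct_reference,
                                     ct_target_cal, ct_reference_cal) {
  stopifnot(is.finite(ct_target), is.finite(ct_reference),
            is.finite(ct_target_cal), is.finite(ct_reference_cal))
  ddct <- (ct_target - ct_reference) - (ct_target_cal - ct_reference_cal)
  2^(-ddct)
}
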