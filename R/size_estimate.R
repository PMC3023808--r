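#' Estimate the interactome size from dataset overlap
#'
#' The capture-recapture (Lincoln-Petersen) form of the hypergeometric
#' moment estimator. Under the assumption that high-throughput true
#' positives are drawn independently of their presence in the
#' literature-curated set, the number of HT true positives found in the LC
#' well-studied subset follows a hypergeometric distribution
#' \eqn{\mathcal{H}(N, m', n)} with \eqn{N} the interactome size, \eqn{m'}
#' the LC well-studied true positives and \eqn{n} the HT true positives.
#' Matching the observed overlap \eqn{k} to its expectation \eqn{n m' / N}
#' gives
#' \deqn{\hat I_s = \frac{TP_{HT} \cdot TP_{LC-WS}}{TP_{overlap}}.}
#'
#' @param tp_ht Estimated number of HT true positives (\eqn{n}); see
#'   [ht_true_positives()].
#' @param tp_lc_ws Estimated number of LC well-studied true positives
#'   (\eqn{m'}); see [lc_ws_true_positives()].
#' @param tp_overlap Observed HT/LC-WS overlap (\eqn{k}), all considered
#'   true positives; must be at least 1.
#' @param conf_level Confidence level for the interval; default 0.95.
#' @param ci_method `"transformed_overlap"` (default; normal interval on
#'   the overlap count, then transformed endpoint-wise, giving an
#'   asymmetric interval) or `"delta"` (first-order delta method on the
#'   estimate itself).
#' @param config Optional named list recording provenance (HT dataset name,
#'   well-studied cutoff, reference FDR, ...), stored unmodified.
#' @return An object of class `interactome_size`: a list with elements
#'   `size`, `tp_ht`, `tp_lc_ws`, `tp_overlap`, `ci` (length-2 vector),
#'   `ci_method`, `conf_level`, `config`.
#' @examples
#' est <- estimate_size(2814, 1922.75, 144)
#' round(est$size) # 37574
#' @export
estimate_size <- function(tp_ht, tp_lc_ws, tp_overlap, conf_level = 0.95,
                          ci_method = c("transformed_overlap", "delta"),
                          config = list()) {
  ci_method <- match.arg(ci_method)
  if (tp_overlap < 1) {
    stop("overlap between the HT dataset and the LC well-studied subset is ",
         "zero: the overlap estimator is unbounded. Lower the well-studied ",
         "cutoff or use a larger HT dataset.")
  }
  if (tp_ht <= 0 || tp_lc_ws <= 0) {
    stop("true-positive counts must be positive")
  }
  if (tp_overlap > min(tp_ht, tp_lc_ws) + 1e-9) {
    stop("overlap cannot exceed either true-positive count")
  }
  size <- tp_ht * tp_lc_ws / tp_overlap
  obj <- structure(list(
    size = size, tp_ht = tp_ht, tp_lc_ws = tp_lc_ws,
    tp_overlap = tp_overlap, ci = c(NA_real_, NA_real_),
    ci_method = ci_method, conf_level = conf_level, config = config
  ), class = "interactome_size")
  obj$ci <- confint(obj, level = conf_level, method = ci_method)
  obj
}

#' Interactome size estimate from the expanded parameter form
#'
#' Expresses the estimate directly in terms of the reference dataset's true
#' positives and the raw overlap counts, making the influence of each
#' parameter explicit:
#' \deqn{\hat I_s = \frac{TP_{ref} \cdot TP_{LC-WS} \cdot |HT \cap LC_{pre}|}
#'   {|ref \cap LC_{pre}| \cdot |HT \cap LC_{WS}|}.}
#' For a single HT dataset this is algebraically identical to composing
#' [chain_fdr()], [ht_true_positives()] and [estimate_size()].
#'
#' @param tp_ref True positives in the reference HT dataset
#'   (`size * (1 - reference FDR)`).
#' @param tp_lc_ws LC well-studied true positives.
#' @param ht_pre2000_overlap Size of the HT intersection with the pre-2000
#'   LC restriction.
#' @param ref_pre2000_overlap Size of the reference dataset's intersection
#'   with the pre-2000 LC restriction.
#' @param ht_lc_ws_overlap Size of the HT intersection with the LC
#'   well-studied subset.
#' @inheritParams estimate_size
#' @return An `interactome_size` object (with back-computed `tp_ht`).
#' @export
estimate_size_expanded <- function(tp_ref, tp_lc_ws, ht_pre2000_overlap,
                                   ref_pre2000_overlap, ht_lc_ws_overlap,
                                   conf_level = 0.95,
                                   ci_method = c("transformed_overlap", "delta"),
                                   config = list()) {
  ci_method <- match.arg(ci_method)
  if (ref_pre2000_overlap <= 0 || ht_lc_ws_overlap <= 0) {
    stop("zero denominator in the expanded size formula")
  }
  if (tp_ref <= 0 || tp_lc_ws <= 0 || ht_pre2000_overlap <= 0) {
    stop("all counts must be positive")
  }
  tp_ht <- tp_ref * ht_pre2000_overlap / ref_pre2000_overlap
  estimate_size(tp_ht, tp_lc_ws, ht_lc_ws_overlap, conf_level = conf_level,
                ci_method = ci_method, config = config)
}

# hypergeometric variance of the overlap count k at N = Is
.overlap_variance <- function(size, tp_ht, tp_lc_ws) {
  p <- tp_lc_ws / size
  v <- tp_ht * p * (1 - p) * (size - tp_ht) / (size - 1)
  max(v, 0)
}

#' Confidence interval for an interactome size estimate
#'
#' Normal-approximation intervals built on the hypergeometric variance of
#' the overlap count \eqn{k}, evaluated at the point estimate:
#' \eqn{Var(k) = n \frac{m'}{I_s}(1 - \frac{m'}{I_s})
#' \frac{I_s - n}{I_s - 1}}.
#'
#' * `"transformed_overlap"` (default): normal interval
#'   \eqn{k \pm z \, sd(k)}, transformed endpoint-wise through
#'   \eqn{I_s = m' n / k}. Asymmetric around the estimate.
#' * `"delta"`: first-order delta method,
#'   \eqn{sd(I_s) = m' n \, sd(k) / k^2}, symmetric interval
#'   \eqn{I_s \pm z \, sd(I_s)}.
#'
#' When the LC set covers all HT true positives (\eqn{k = n}) the variance
#' is zero and the interval collapses onto the estimate.
#'
#' @param object An `interactome_size` object.
#' @param parm Ignored (single-parameter model).
#' @param level Confidence level in (0, 1).
#' @param method CI method, see above; defaults to the method stored in the
#'   object.
#' @param ... Ignored.
#' @return Named numeric vector `c(lower, upper)`. The upper bound is `Inf`
#'   when the lower overlap bound is non-positive.
#' @export
confint.interactome_size <- function(object, parm, level = 0.95,
                                     method = NULL, ...) {
  if (level <= 0 || level >= 1) stop("confidence level must be in (0, 1)")
  method <- if (is.null(method)) object$ci_method else
    match.arg(method, c("transformed_overlap", "delta"))
  z <- stats::qnorm(1 - (1 - level) / 2)
  k <- object$tp_overlap
  m <- object$tp_lc_ws
  n <- object$tp_ht
  sd_k <- sqrt(.overlap_variance(object$size, n, m))
  if (method == "delta") {
    sd_is <- m * n * sd_k / k^2
    ci <- object$size + c(-1, 1) * z * sd_is
  } else {
    k_lo <- k - z * sd_k
    k_hi <- k + z * sd_k
    upper <- if (k_lo > 0) m * n / k_lo else Inf
    ci <- c(m * n / k_hi, upper)
  }
  stats::setNames(ci, c("lower", "upper"))
}

#' @export
print.interactome_size <- function(x, digits = 0, ...) {
  cat("Interactome size estimate (hypergeometric overlap estimator)\n")
  cat(sprintf("  estimated size: %s interactions\n",
              format(round(x$size, digits), big.mark = ",")))
  cat(sprintf("  %d%% CI (%s): %s - %s\n", round(100 * x$conf_level),
              x$ci_method,
              format(round(x$ci[1L], digits), big.mark = ","),
              format(round(x$ci[2L], digits), big.mark = ",")))
  invisible(x)
}

#' @export
summary.interactome_size <- function(object, ...) {
  structure(list(est = object), class = "summary.interactome_size")
}

#' @export
print.summary.interactome_size <- function(x, ...) {
  e <- x$est
  print(e)
  cat("components:\n")
  cat(sprintf("  HT true positives (n):            %.2f\n", e$tp_ht))
  cat(sprintf("  LC well-studied true pos. (m'):   %.2f\n", e$tp_lc_ws))
  cat(sprintf("  overlap true positives (k):       %g\n", e$tp_overlap))
  if (length(e$config)) {
    cat("parameters:\n")
    for (nm in names(e$config)) {
      cat(sprintf("  %s: %s\n", nm, paste(e$config[[nm]], collapse = ", ")))
    }
  }
  invisible(x)
}

#' @export
coef.interactome_size <- function(object, ...) {
  c(size = object$size, tp_ht = object$tp_ht, tp_lc_ws = object$tp_lc_ws,
    tp_overlap = object$tp_overlap)
}

#' Simulate overlap counts implied by a size estimate
#'
#' Draws replicate overlap counts from the fitted hypergeometric model
#' \eqn{\mathcal{H}(\hat I_s, m', n)} — a parametric-bootstrap view of how
#' variable the observed overlap would be if the point estimate were the
#' truth.
#'
#' @param object An `interactome_size` object.
#' @param nsim Number of replicates.
#' @param seed Optional integer seed.
#' @param ... Ignored.
#' @return Integer vector of simulated overlap counts, length `nsim`.
#' @export
simulate.interactome_size <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  N <- max(round(object$size), ceiling(object$tp_ht), ceiling(object$tp_lc_ws))
  m <- round(object$tp_lc_ws)
  n <- round(object$tp_ht)
  stats::rhyper(nsim, m, N - m, n)
}

#' False-negative rate of the well-studied LC subset
#'
#' Estimates how many genuine interactions involving well-studied proteins
#' the literature misses, by comparing the expected true positives in the
#' well-studied restriction of an HT dataset with those confirmed in LC:
#' \deqn{FNR = 1 - \frac{TP_{HT_{WS}} \cap LC}{TP_{HT_{WS}}}.}
#' The intersection is counted as all-true-positive; the HT true-positive
#' count uses `|HT_WS| * (1 - FDR)` (or the per-component sum for unions).
#'
#' @param ht_ws HT `interaction_dataset` restricted to well-studied pairs.
#' @param lc Full LC `interaction_dataset`.
#' @param fdr_ht_ws FDR applied to `ht_ws` (single-dataset case).
#' @param component_sizes,component_fdrs Optional named vectors for union
#'   datasets (well-studied component sizes and their FDRs); override
#'   `fdr_ht_ws` when supplied.
#' @return An object of class `fnr_estimate`: list with `fnr`, `tp_ht_ws`,
#'   `tp_overlap_ws`.
#' @export
lc_ws_false_negative_rate <- function(ht_ws, lc, fdr_ht_ws = NULL,
                                      component_sizes = NULL,
                                      component_fdrs = NULL) {
  if (ds_size(ht_ws) == 0L) stop("empty well-studied HT dataset")
  tp_ht_ws <- if (!is.null(component_sizes)) {
    ht_true_positives(ds_size(ht_ws), component_sizes, component_fdrs)
  } else {
    if (is.null(fdr_ht_ws)) stop("supply fdr_ht_ws or component sizes/FDRs")
    ds_size(ht_ws) * (1 - fdr_ht_ws)
  }
  if (tp_ht_ws <= 0) stop("estimated HT well-studied true positives is zero")
  tp_overlap_ws <- overlap_true_positives(ht_ws, lc)
  fnr <- min(1, max(0, 1 - tp_overlap_ws / tp_ht_ws))
  structure(list(fnr = fnr, tp_ht_ws = tp_ht_ws,
                 tp_overlap_ws = tp_overlap_ws),
            class = "fnr_estimate")
}

#' @export
print.fnr_estimate <- function(x, ...) {
  cat(sprintf(
    "LC well-studied false-negative rate: %.2f\n  (%g overlap TPs of %.2f expected HT-WS TPs)\n",
    x$fnr, x$tp_overlap_ws, x$tp_ht_ws))
  invisible(x)
}
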