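#' Proportion of an HT dataset covered by a reference LC dataset
#'
#' The fraction A/(A+B+C) of high-throughput interactions present in a
#' literature-curated reference (typically the pre-2000 restriction of the
#' curated set, so that targeted confirmations of HT hits cannot inflate
#' the overlap).
#'
#' @param ht High-throughput `interaction_dataset`.
#' @param lc_ref Reference literature-curated `interaction_dataset`.
#' @return Fraction in `[0, 1]`.
#' @export
coverage_proportion <- function(ht, lc_ref) {
  if (ds_size(ht) == 0L) stop("coverage proportion undefined for an empty HT dataset")
  sum(ds_keys(ht) %in% ds_keys(lc_ref)) / ds_size(ht)
}

#' Coverage ratio between two HT datasets
#'
#' The ratio alpha of the target dataset's LC coverage to the reference
#' dataset's LC coverage; the pivot of the FDR chaining relation.
#'
#' @param prop_target Coverage proportion of the target dataset.
#' @param prop_ref Coverage proportion of the reference dataset (> 0).
#' @return Positive real `prop_target / prop_ref`.
#' @export
alpha_ratio <- function(prop_target, prop_ref) {
  if (any(prop_ref <= 0)) stop("reference coverage proportion must be > 0")
  prop_target / prop_ref
}

#' Chain a false-discovery rate from a reference dataset
#'
#' Derives the FDR of a target HT dataset from a reference HT dataset's
#' FDR, under the hypothesis that the LC reference covers the same fraction
#' of true positives in every HT dataset:
#' \deqn{FDR_{target} = \alpha \cdot FDR_{ref} + 1 - \alpha,\quad
#'       \alpha = prop_{target} / prop_{ref}.}
#' A raw value outside `[0, 1]` (possible when rounded input proportions
#' make alpha exceed `1/(1 - FDR_ref)`) is clamped with a warning.
#'
#' @param prop_target,prop_ref LC-reference coverage proportions of the
#'   target and reference datasets.
#' @param fdr_ref Reference FDR in `[0, 1]`.
#' @return Chained FDR in `[0, 1]`.
#' @examples
#' chain_fdr(0.0831, 0.0734, 0.25) # ~0.15
#' @export
chain_fdr <- function(prop_target, prop_ref, fdr_ref) {
  stopifnot(fdr_ref >= 0, fdr_ref <= 1,
            prop_target >= 0, prop_target <= 1, prop_ref <= 1)
  alpha <- alpha_ratio(prop_target, prop_ref)
  fdr <- alpha * fdr_ref + 1 - alpha
  if (any(fdr < 0) || any(fdr > 1)) {
    warning("chained FDR outside [0, 1]; clamped")
    fdr <- pmin(1, pmax(0, fdr))
  }
  fdr
}

#' Build a per-dataset error-rate table by FDR chaining
#'
#' Computes each HT dataset's coverage by the LC reference and chains its
#' FDR from the designated reference dataset.
#'
#' @param ht_list Named list of HT `interaction_dataset`s.
#' @param lc_ref Reference LC `interaction_dataset` (pre-2000 restriction).
#' @param reference Name of the reference dataset in `ht_list`; default
#'   `"CCSB-YI1"`.
#' @param reference_fdr FDR assumed for the reference; default 0.25.
#' @param lc_unique_fp_rate False-positive rate assigned to single-paper LC
#'   interactions absent from HT; default 0.35.
#' @return An object of class `error_rate_table`: a data frame with columns
#'   `dataset`, `size`, `coverage`, `alpha`, `fdr`, `is_reference`, plus
#'   attributes `reference`, `reference_fdr`, `lc_unique_fp_rate`.
#' @export
error_rate_table <- function(ht_list, lc_ref, reference = "CCSB-YI1",
                             reference_fdr = 0.25, lc_unique_fp_rate = 0.35) {
  if (!reference %in% names(ht_list)) {
    stop("reference dataset ", sQuote(reference), " not in ht_list")
  }
  cov <- vapply(ht_list, coverage_proportion, numeric(1L), lc_ref = lc_ref)
  alpha <- alpha_ratio(cov, cov[[reference]])
  fdr <- vapply(cov, chain_fdr, numeric(1L),
                prop_ref = cov[[reference]], fdr_ref = reference_fdr)
  out <- data.frame(
    dataset = names(ht_list),
    size = vapply(ht_list, ds_size, integer(1L)),
    coverage = unname(cov),
    alpha = unname(alpha),
    fdr = unname(fdr),
    is_reference = names(ht_list) == reference,
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(out, class = c("error_rate_table", "data.frame"),
            reference = reference, reference_fdr = reference_fdr,
            lc_unique_fp_rate = lc_unique_fp_rate)
}

#' Write / read an error-rate table as TSV
#'
#' @param x An `error_rate_table`.
#' @param path Output (input) TSV path.
#' @return `write_error_rate_table` returns `path` invisibly;
#'   `read_error_rate_table` returns an `error_rate_table`.
#' @export
write_error_rate_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_error_rate_table
#' @param lc_unique_fp_rate FP rate restored on read (not stored per row).
#' @export
read_error_rate_table <- function(path, lc_unique_fp_rate = 0.35) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  ref <- tab$dataset[tab$is_reference][1L]
  structure(tab, class = c("error_rate_table", "data.frame"),
            reference = ref, reference_fdr = tab$fdr[tab$is_reference][1L],
            lc_unique_fp_rate = lc_unique_fp_rate)
}

#' Expected number of true positives in an HT dataset or union
#'
#' For a union of screens, each component contributes its own expected
#' false-positive mass while the union size counts shared pairs once:
#' \deqn{TP_{HT} = |HT| - \sum_i |HT_i| \cdot FDR_i.}
#' For a single dataset this reduces to `|HT| * (1 - FDR)`.
#'
#' @param ht_size Size of the (deduplicated) HT dataset or union.
#' @param component_sizes Named numeric vector of component sizes.
#' @param component_fdrs Named numeric vector (or `error_rate_table`) giving
#'   the FDR of every component named in `component_sizes`.
#' @return Expected true-positive count (real, not rounded).
#' @export
ht_true_positives <- function(ht_size, component_sizes, component_fdrs) {
  if (inherits(component_fdrs, "error_rate_table")) {
    component_fdrs <- stats::setNames(component_fdrs$fdr, component_fdrs$dataset)
  }
  missing_fdr <- setdiff(names(component_sizes), names(component_fdrs))
  if (length(missing_fdr)) {
    stop("no FDR configured for component(s): ",
         paste(missing_fdr, collapse = ", "))
  }
  ht_size - sum(component_sizes * component_fdrs[names(component_sizes)])
}

#' Expected true positives in the well-studied LC subset
#'
#' Removes the expected false positives: a fraction `fp_rate` of the
#' single-paper interactions not found in the HT dataset (the only LC
#' records considered at risk; multi-paper or HT-confirmed interactions
#' are taken as genuine).
#'
#' @param lc_ws_size Number of LC interactions involving well-studied
#'   proteins.
#' @param unique_ws_size Number of those supported by a single paper and
#'   absent from the HT dataset under consideration.
#' @param fp_rate Recuration-based false-positive rate; default 0.35.
#' @return `lc_ws_size - fp_rate * unique_ws_size` (real, not rounded).
#' @export
lc_ws_true_positives <- function(lc_ws_size, unique_ws_size, fp_rate = 0.35) {
  stopifnot(fp_rate >= 0, fp_rate <= 1)
  if (any(unique_ws_size > lc_ws_size)) {
    stop("unique subset cannot be larger than the well-studied LC set")
  }
  lc_ws_size - fp_rate * unique_ws_size
}

#' True positives in the HT / LC intersection
#'
#' Interactions detected by two independent approaches are all considered
#' genuine, so the overlap true-positive count is the exact intersection
#' size.
#'
#' @param ht,lc_ws `interaction_dataset` objects.
#' @return Integer intersection size.
#' @export
overlap_true_positives <- function(ht, lc_ws) {
  sum(ds_keys(ht) %in% ds_keys(lc_ws))
}
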