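resolve_ht_target <- function(ht_list, ht) {
  if (length(ht) == 1L && ht %in% names(ht_list)) {
    list(target = ht_list[[ht]], components = ht, name = ht)
  } else {
    comps <- if (length(ht) == 1L && tolower(ht) %in% c("ht-union", "union")) {
      names(ht_list)
    } else {
      missing <- setdiff(ht, names(ht_list))
      if (length(missing)) {
        stop("unknown HT dataset(s): ", paste(missing, collapse = ", "))
      }
      ht
    }
    nm <- if (length(comps) == length(ht_list)) "HT-Union" else
      paste(comps, collapse = "+")
    list(target = union_datasets(ht_list[comps], name = nm),
         components = comps, name = nm)
  }
}

#' Run the full interactome size estimation pipeline
#'
#' Chains every stage of the analysis on in-memory datasets: pre-2000
#' restriction of the curated set, per-dataset FDR chaining from the
#' reference screen, well-studied restriction, single-paper unique subset,
#' true-positive accounting and the hypergeometric overlap estimate with
#' its confidence interval. The returned report mirrors the calculation
#' steps (well-studied LC size, LC true positives, HT true positives,
#' overlap, estimated size).
#'
#' @param lc Curated low-throughput binary physical `interaction_dataset`
#'   (see [filter_binary_physical_low_throughput()]).
#' @param levels `study_levels` for the organism.
#' @param ht_list Named list of HT `interaction_dataset`s (the roster used
#'   for FDR chaining; must contain the reference dataset).
#' @param ht HT dataset to estimate with: a name from `ht_list`, a vector
#'   of names (union of those components), or `"HT-Union"` (default, union
#'   of the whole roster).
#' @param cutoff Well-studied cutoff (papers per protein); default 125.
#' @param ws_mode `"any"` (default) or `"both"` endpoints well-studied.
#' @param reference,reference_fdr Reference dataset name and its assumed
#'   FDR; defaults `"CCSB-YI1"` and 0.25.
#' @param lc_unique_fp_rate FP rate of single-paper unique LC interactions;
#'   default 0.35.
#' @param pre2000_year Year bound for the FDR-chaining restriction; default
#'   2000.
#' @param conf_level,ci_method Passed to [estimate_size()].
#' @return An object of class `interactome_fit`: list with elements
#'   `estimate` (an `interactome_size`), `report` (data frame of named
#'   calculation steps), `error_table` (the `error_rate_table`), and the
#'   intermediate datasets (`lc_ws`, `unique_ws`, `ht_target`).
#' @export
run_full_estimation <- function(lc, levels, ht_list, ht = "HT-Union",
                                cutoff = 125, ws_mode = c("any", "both"),
                                reference = "CCSB-YI1", reference_fdr = 0.25,
                                lc_unique_fp_rate = 0.35, pre2000_year = 2000,
                                conf_level = 0.95,
                                ci_method = c("transformed_overlap", "delta")) {
  ws_mode <- match.arg(ws_mode)
  ci_method <- match.arg(ci_method)
  lc_pre <- restrict_before_year(lc, pre2000_year)
  if (ds_size(lc_pre) == 0L) {
    stop("stage pre-2000 restriction: no LC interaction predates ", pre2000_year)
  }
  err <- error_rate_table(ht_list, lc_pre, reference = reference,
                          reference_fdr = reference_fdr,
                          lc_unique_fp_rate = lc_unique_fp_rate)
  ws <- well_studied_set(levels, cutoff)
  lc_ws <- restrict_well_studied(lc, ws, mode = ws_mode)
  if (ds_size(lc_ws) == 0L) {
    stop("stage well-studied restriction: no LC interaction involves a ",
         "well-studied protein at cutoff ", cutoff)
  }
  tgt <- resolve_ht_target(ht_list, ht)
  uniq <- single_paper_unique(lc_ws, tgt$target)
  tp_lc <- lc_ws_true_positives(ds_size(lc_ws), ds_size(uniq),
                                fp_rate = lc_unique_fp_rate)
  comp_sizes <- vapply(ht_list[tgt$components], ds_size, integer(1L))
  tp_ht <- ht_true_positives(ds_size(tgt$target), comp_sizes, err)
  if (tp_ht <= 0) {
    stop("stage HT true positives: chained FDRs leave no true positives in ",
         tgt$name)
  }
  k <- overlap_true_positives(tgt$target, lc_ws)
  est <- estimate_size(tp_ht, tp_lc, k, conf_level = conf_level,
                       ci_method = ci_method,
                       config = list(ht = tgt$name, cutoff = cutoff,
                                     ws_mode = ws_mode, reference = reference,
                                     reference_fdr = reference_fdr,
                                     lc_unique_fp_rate = lc_unique_fp_rate,
                                     pre2000_year = pre2000_year))
  report <- data.frame(
    quantity = c("LC well-studied size", "LC unique (single-paper) size",
                 "LC well-studied TPs", "HT size", "HT TPs",
                 "HT ∩ LC well-studied", "Estimated size",
                 "CI lower", "CI upper"),
    value = c(ds_size(lc_ws), ds_size(uniq), round(tp_lc, 2),
              ds_size(tgt$target), round(tp_ht, 2), k,
              round(est$size), round(est$ci[1L]), round(est$ci[2L])),
    stringsAsFactors = FALSE
  )
  structure(list(estimate = est, report = report, error_table = err,
                 lc_ws = lc_ws, unique_ws = uniq, ht_target = tgt$target),
            class = "interactome_fit")
}

#' @export
print.interactome_fit <- function(x, ...) {
  cat("Interactome size estimation —", x$estimate$config$ht, "\n")
  rep <- x$report
  w <- max(nchar(rep$quantity))
  for (i in seq_len(nrow(rep))) {
    cat(sprintf("  %-*s %s\n", w, rep$quantity[i],
                format(rep$value[i], big.mark = ",")))
  }
  invisible(x)
}

run_one_sweep_row <- function(lc, levels, ht_list, ht, cutoff, ws_mode,
                              reference, reference_fdr, lc_unique_fp_rate,
                              pre2000_year) {
  res <- tryCatch(
    run_full_estimation(lc, levels, ht_list, ht = ht, cutoff = cutoff,
                        ws_mode = ws_mode, reference = reference,
                        reference_fdr = reference_fdr,
                        lc_unique_fp_rate = lc_unique_fp_rate,
                        pre2000_year = pre2000_year),
    error = function(e) e)
  if (inherits(res, "error")) {
    # zero overlap (or an empty stage) flags the row instead of failing
    return(data.frame(dataset = if (length(ht) > 1L) "HT-Union" else ht,
                      lc_ws_size = NA_integer_, tp_lc_ws = NA_real_,
                      tp_ht = NA_real_, overlap = NA_integer_,
                      size = NA_real_, flagged = TRUE,
                      stringsAsFactors = FALSE))
  }
  e <- res$estimate
  data.frame(dataset = e$config$ht, lc_ws_size = ds_size(res$lc_ws),
             tp_lc_ws = e$tp_lc_ws, tp_ht = e$tp_ht, overlap = e$tp_overlap,
             size = e$size, flagged = FALSE, stringsAsFactors = FALSE)
}

#' Sweep the well-studied cutoff
#'
#' Recomputes the full estimate — well-studied set, LC restriction, unique
#' subset, overlap — at each cutoff, for each HT dataset (and their union).
#'
#' @inheritParams run_full_estimation
#' @param cutoffs Increasing vector of well-studied cutoffs.
#' @param datasets HT datasets to sweep: names from `ht_list`, with
#'   `"HT-Union"` for the union; defaults to every dataset plus the union.
#' @return An object of classes `interactome_sweep`/`data.frame` with one
#'   row per (cutoff, dataset): columns `parameter`, `dataset`,
#'   `lc_ws_size`, `tp_lc_ws`, `tp_ht`, `overlap`, `size`, `flagged`.
#'   Attribute `parameter` is `"well_studied_cutoff"`.
#' @export
sweep_well_studied_cutoff <- function(lc, levels, ht_list,
                                      cutoffs = seq(100, 150, by = 5),
                                      datasets = c(names(ht_list), "HT-Union"),
                                      ws_mode = "any", reference = "CCSB-YI1",
                                      reference_fdr = 0.25,
                                      lc_unique_fp_rate = 0.35,
                                      pre2000_year = 2000) {
  stopifnot(length(cutoffs) > 0, !is.unsorted(cutoffs, strictly = TRUE))
  rows <- lapply(cutoffs, function(cut) {
    do.call(rbind, lapply(datasets, function(d) {
      r <- run_one_sweep_row(lc, levels, ht_list, ht = d, cutoff = cut,
                             ws_mode = ws_mode, reference = reference,
                             reference_fdr = reference_fdr,
                             lc_unique_fp_rate = lc_unique_fp_rate,
                             pre2000_year = pre2000_year)
      cbind(parameter = cut, r)
    }))
  })
  structure(do.call(rbind, rows),
            class = c("interactome_sweep", "data.frame"),
            parameter = "well_studied_cutoff")
}

#' Sweep the reference FDR
#'
#' Recomputes every chained FDR, the HT true-positive counts and the size
#' estimate for each assumed reference-dataset FDR, at a fixed well-studied
#' cutoff.
#'
#' @inheritParams sweep_well_studied_cutoff
#' @param fdr_values Vector of reference FDR values in `[0, 1]`.
#' @param cutoff Fixed well-studied cutoff; default 125.
#' @return An `interactome_sweep` data frame (attribute `parameter` is
#'   `"reference_fdr"`).
#' @export
sweep_reference_fdr <- function(lc, levels, ht_list,
                                fdr_values = seq(0.15, 0.35, by = 0.05),
                                datasets = c(names(ht_list), "HT-Union"),
                                cutoff = 125, ws_mode = "any",
                                reference = "CCSB-YI1",
                                lc_unique_fp_rate = 0.35,
                                pre2000_year = 2000) {
  stopifnot(length(fdr_values) > 0, all(fdr_values >= 0 & fdr_values <= 1))
  rows <- lapply(fdr_values, function(f) {
    do.call(rbind, lapply(datasets, function(d) {
      r <- run_one_sweep_row(lc, levels, ht_list, ht = d, cutoff = cutoff,
                             ws_mode = ws_mode, reference = reference,
                             reference_fdr = f,
                             lc_unique_fp_rate = lc_unique_fp_rate,
                             pre2000_year = pre2000_year)
      cbind(parameter = f, r)
    }))
  })
  structure(do.call(rbind, rows),
            class = c("interactome_sweep", "data.frame"),
            parameter = "reference_fdr")
}

#' Plot a parameter sweep
#'
#' One line per HT dataset, estimated interactome size against the swept
#' parameter (well-studied cutoff or reference FDR).
#'
#' @param x An `interactome_sweep`.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.interactome_sweep <- function(x, ...) {
  param <- attr(x, "parameter")
  ds <- unique(x$dataset)
  pv <- sort(unique(x$parameter))
  mat <- sapply(ds, function(d) {
    x$size[x$dataset == d][match(pv, x$parameter[x$dataset == d])]
  })
  graphics::matplot(pv, mat, type = "b", pch = seq_along(ds), lty = 1,
                    xlab = if (param == "reference_fdr") "reference FDR"
                           else "well-studied cutoff (papers)",
                    ylab = "estimated interactome size", ...)
  graphics::legend("topleft", legend = ds, pch = seq_along(ds),
                   col = seq_along(ds), bty = "n", cex = 0.8)
  invisible(x)
}
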