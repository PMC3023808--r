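#' Parameter-recovery experiment on synthetic worlds
#'
#' Generates replicate synthetic worlds, draws one LC and one HT sample
#' from each, and runs the overlap estimator in two variants: "naive"
#' (all LC interactions) and "ws" (LC restricted to pairs involving
#' well-studied proteins). With unbiased sampling both variants should
#' recover the true interactome size; with detectability-biased curation
#' the naive variant underestimates and the well-studied restriction
#' moves the estimate back toward the truth.
#'
#' Within each replicate the HT true-positive count is estimated as
#' `|HT| * (1 - FDR)` using the sample's realised FDR (the oracle label
#' attached by [sample_ht_dataset()]), and the LC true positives apply the
#' configured single-paper false-positive correction via
#' [single_paper_unique()] when `lc_args$fp_rate > 0`.
#'
#' @param n_replicates Number of replicate worlds.
#' @param world_args Named list of arguments for [generate_world()].
#' @param ht_args Named list of arguments for [sample_ht_dataset()].
#' @param lc_args Named list of arguments for [sample_lc_dataset()].
#' @param ws_cutoff Well-studied cutoff for the restricted variant;
#'   default 125.
#' @param ws_mode `"any"` or `"both"`, see [restrict_well_studied()].
#' @param conf_level Confidence level of the per-replicate intervals.
#' @param seed Integer seed for the whole experiment (one stream drives
#'   all replicates, so the report is fully reproducible).
#' @return An object of class `recovery_report`: list with `replicates`
#'   (data frame: `true_n`, `est_naive`, `est_ws`, CI bounds and coverage
#'   flags per variant) and `summary` (mean relative bias, RMSE and CI
#'   coverage per variant).
#' @export
recovery_experiment <- function(n_replicates = 200,
                                world_args = list(),
                                ht_args = list(),
                                lc_args = list(),
                                ws_cutoff = 125, ws_mode = "any",
                                conf_level = 0.95, seed = 1) {
  stopifnot(n_replicates >= 1)
  set.seed(seed)
  fp_rate <- if (is.null(lc_args$fp_rate)) 0 else lc_args$fp_rate
  one <- function(rep_i) {
    world <- do.call(generate_world, world_args)
    ht <- do.call(sample_ht_dataset, c(list(world = world), ht_args))
    lc <- do.call(sample_lc_dataset, c(list(world = world), lc_args))
    tp_ht <- ds_size(ht) * (1 - attr(ht, "true_fdr"))
    est_variant <- function(lc_sub) {
      k <- overlap_true_positives(ht, lc_sub)
      if (k < 1) return(NULL)
      tp_lc <- if (fp_rate > 0) {
        lc_ws_true_positives(ds_size(lc_sub),
                             ds_size(single_paper_unique(lc_sub, ht)),
                             fp_rate = fp_rate)
      } else {
        ds_size(lc_sub)
      }
      estimate_size(tp_ht, tp_lc, k, conf_level = conf_level)
    }
    naive <- est_variant(lc)
    ws <- est_variant(restrict_well_studied(
      lc, well_studied_set(world$study_levels, ws_cutoff), mode = ws_mode))
    grab <- function(e) {
      if (is.null(e)) c(NA_real_, NA_real_, NA_real_)
      else c(e$size, e$ci[1L], e$ci[2L])
    }
    c(world$n_true, grab(naive), grab(ws))
  }
  mat <- t(vapply(seq_len(n_replicates), one, numeric(7L)))
  reps <- data.frame(
    replicate = seq_len(n_replicates),
    true_n = mat[, 1L],
    est_naive = mat[, 2L], ci_lo_naive = mat[, 3L], ci_hi_naive = mat[, 4L],
    est_ws = mat[, 5L], ci_lo_ws = mat[, 6L], ci_hi_ws = mat[, 7L]
  )
  reps$covered_naive <- reps$ci_lo_naive <= reps$true_n &
    reps$true_n <= reps$ci_hi_naive
  reps$covered_ws <- reps$ci_lo_ws <= reps$true_n &
    reps$true_n <= reps$ci_hi_ws
  summarise <- function(est, covered) {
    rel <- (est - reps$true_n) / reps$true_n
    c(mean_estimate = mean(est, na.rm = TRUE),
      mean_rel_bias = mean(rel, na.rm = TRUE),
      rmse = sqrt(mean((est - reps$true_n)^2, na.rm = TRUE)),
      ci_coverage = mean(covered, na.rm = TRUE),
      n_failed = sum(is.na(est)))
  }
  structure(list(
    replicates = reps,
    summary = rbind(naive = summarise(reps$est_naive, reps$covered_naive),
                    ws = summarise(reps$est_ws, reps$covered_ws)),
    config = list(n_replicates = n_replicates, world_args = world_args,
                  ht_args = ht_args, lc_args = lc_args,
                  ws_cutoff = ws_cutoff, ws_mode = ws_mode, seed = seed)
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Synthetic recovery experiment:", nrow(x$replicates), "replicates\n")
  cat(sprintf("  true N (mean): %.0f\n", mean(x$replicates$true_n)))
  s <- x$summary
  for (v in rownames(s)) {
    cat(sprintf(
      "  %-6s mean estimate %.0f (rel. bias %+.1f%%), RMSE %.0f, CI coverage %.2f\n",
      v, s[v, "mean_estimate"], 100 * s[v, "mean_rel_bias"],
      s[v, "rmse"], s[v, "ci_coverage"]))
  }
  invisible(x)
}
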