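#' Bin interactions by IST hit count
#'
#' Greedy ascending binning of interactions by their interaction-sequence-tag
#' (IST) hit count. Walking IST values in increasing order, a bin closes at
#' the first value where the cumulative member count reaches
#' `min_bin_size` — but never between two interactions sharing the same IST
#' count, so bins of frequent values (particularly single hits) can be
#' larger than the minimum. A trailing group smaller than `min_bin_size`
#' stays in the last bin.
#'
#' @param ist_count Integer vector of IST hits, all `>= 1`.
#' @param min_bin_size Minimum interactions per bin; default 200.
#' @return Data frame with one row per bin: `bin`, `weighted_mean_ist`
#'   (size-weighted mean of member IST counts), `n_interactions`, and a
#'   list-column `members` of input indices. Bins partition the input.
#' @export
bin_by_ist <- function(ist_count, min_bin_size = 200) {
  if (any(is.na(ist_count)) || any(ist_count < 1)) {
    stop("every interaction must carry an IST count >= 1")
  }
  n <- length(ist_count)
  if (n < min_bin_size) {
    warning("fewer interactions than min_bin_size; returning a single bin")
  }
  ord <- order(ist_count)
  vals <- ist_count[ord]
  runs <- rle(as.numeric(vals))
  bin_of_run <- integer(length(runs$lengths))
  bin <- 1L
  acc <- 0L
  for (i in seq_along(runs$lengths)) {
    bin_of_run[i] <- bin
    acc <- acc + runs$lengths[i]
    if (acc >= min_bin_size && i < length(runs$lengths)) {
      bin <- bin + 1L
      acc <- 0L
    }
  }
  # a trailing underfull bin is merged into its predecessor
  if (bin > 1L && acc > 0L && acc < min_bin_size) {
    bin_of_run[bin_of_run == bin] <- bin - 1L
  }
  bin_id <- rep(bin_of_run, runs$lengths)
  idx <- split(ord, bin_id)
  data.frame(
    bin = seq_along(idx),
    weighted_mean_ist = vapply(idx, function(i) mean(ist_count[i]), numeric(1L)),
    n_interactions = lengths(idx),
    members = I(unname(idx)),
    row.names = NULL
  )
}

#' LC coverage as a function of IST hit count
#'
#' Bins an IST-annotated screen (Ito-Full style) by increasing IST count and
#' computes, per bin, the proportion of member interactions present in the
#' literature-curated set. A rising curve shows that literature curation is
#' enriched in interactions that the Y2H assay finds easily.
#'
#' @param ht_ist `interaction_dataset` whose records carry IST counts.
#' @param lc Literature-curated `interaction_dataset` (run against both the
#'   full set and its pre-2000 restriction to rule out HT-confirmation
#'   artefacts).
#' @param min_bin_size Minimum interactions per bin; default 200.
#' @return Data frame with columns `weighted_mean_ist`, `n_interactions`,
#'   `lc_coverage`.
#' @export
ist_coverage_curve <- function(ht_ist, lc, min_bin_size = 200) {
  if (all(is.na(ht_ist$ist))) stop("dataset carries no IST counts")
  bins <- bin_by_ist(ht_ist$ist, min_bin_size = min_bin_size)
  in_lc <- ds_keys(ht_ist) %in% ds_keys(lc)
  data.frame(
    weighted_mean_ist = bins$weighted_mean_ist,
    n_interactions = bins$n_interactions,
    lc_coverage = vapply(bins$members, function(i) mean(in_lc[i]), numeric(1L))
  )
}

#' Binned log-log regression of degree on study level
#'
#' Core regression behind the degree-versus-study-level diagnostic:
#' proteins are sorted by paper count (ties broken by id for determinism)
#' and grouped into consecutive bins of `bin_size`; a final underfull bin
#' is merged into its predecessor. Ordinary least squares is fitted on
#' (log10 mean papers, log10 mean degree) over bins where both means are
#' positive.
#'
#' @param papers Numeric vector of per-protein paper counts.
#' @param degree Numeric vector of per-protein degrees.
#' @param ids Optional protein ids used for deterministic tie-breaking.
#' @param bin_size Proteins per bin; default 5.
#' @return An object of class `study_regression`: list with `slope`,
#'   `r_squared`, `p_value`, `n_bins`, and the binned means (`bin_papers`,
#'   `bin_degree`).
#' @export
binned_loglog_regression <- function(papers, degree, ids = NULL, bin_size = 5) {
  stopifnot(length(papers) == length(degree))
  if (is.null(ids)) ids <- as.character(seq_along(papers))
  ord <- order(papers, ids)
  papers <- papers[ord]
  degree <- degree[ord]
  n <- length(papers)
  bin <- (seq_len(n) - 1L) %/% bin_size + 1L
  if (n %% bin_size != 0L && max(bin) > 1L) {
    bin[bin == max(bin)] <- max(bin) - 1L
  }
  mp <- tapply(papers, bin, mean)
  md <- tapply(degree, bin, mean)
  use <- mp > 0 & md > 0
  if (sum(use) < 3L) {
    stop("fewer than 3 usable bins for the log-log regression")
  }
  fit <- stats::lm(log10(md[use]) ~ log10(mp[use]))
  sm <- summary(fit)
  structure(list(
    slope = unname(stats::coef(fit)[2L]),
    r_squared = sm$r.squared,
    p_value = sm$coefficients[2L, 4L],
    n_bins = sum(use),
    bin_papers = unname(mp[use]),
    bin_degree = unname(md[use])
  ), class = "study_regression")
}

#' @export
print.study_regression <- function(x, ...) {
  cat(sprintf(
    "Binned log-log degree ~ study-level regression\n  slope = %.3f, R^2 = %.3f, p = %.3g (%d bins)\n",
    x$slope, x$r_squared, x$p_value, x$n_bins))
  invisible(x)
}

#' Degree versus study level regression for a dataset
#'
#' Computes each protein's degree in the dataset (proteins absent from the
#' dataset, i.e. of degree zero, are excluded — their log-degree is
#' undefined) and its paper count, then delegates to
#' [binned_loglog_regression()]. A steep positive slope in the curated set
#' versus a flat slope in an unbiased screen is the signature of
#' study-driven curation bias.
#'
#' @param ds An `interaction_dataset`.
#' @param levels A `study_levels` object.
#' @param bin_size Proteins per regression point; default 5.
#' @return A `study_regression` object.
#' @export
degree_vs_study_regression <- function(ds, levels, bin_size = 5) {
  if (ds_size(ds) == 0L) stop("empty dataset")
  ends <- c(ds$pairs$a, ds$pairs$b)
  # a self-pair contributes degree 2 to its protein, like a loop edge
  deg <- table(ends)
  prot <- names(deg)
  binned_loglog_regression(study_level_of(levels, prot), as.numeric(deg),
                           ids = prot, bin_size = bin_size)
}

#' HT coverage of the well-studied LC subset across cutoffs
#'
#' For each well-studied cutoff and HT dataset, the proportion of LC
#' interactions involving well-studied proteins that the HT dataset also
#' contains. Falling coverage at higher cutoffs indicates that well-studied
#' proteins contribute interactions HT assays miss.
#'
#' @param lc Literature-curated `interaction_dataset`.
#' @param ht_list Named list of HT `interaction_dataset`s.
#' @param levels `study_levels`.
#' @param cutoffs Vector of well-studied cutoffs.
#' @param ws_mode `"any"` or `"both"`, see [restrict_well_studied()].
#' @return Data frame with columns `cutoff`, `dataset`, `lc_ws_size`,
#'   `coverage`, `flagged` (TRUE when the well-studied LC set is empty).
#' @export
ht_coverage_vs_cutoff <- function(lc, ht_list, levels,
                                  cutoffs = seq(100, 150, by = 5),
                                  ws_mode = "any") {
  rows <- lapply(cutoffs, function(cut) {
    lc_ws <- restrict_well_studied(lc, well_studied_set(levels, cut),
                                   mode = ws_mode)
    do.call(rbind, lapply(names(ht_list), function(d) {
      m <- ds_size(lc_ws)
      data.frame(cutoff = cut, dataset = d, lc_ws_size = m,
                 coverage = if (m > 0)
                   sum(ds_keys(lc_ws) %in% ds_keys(ht_list[[d]])) / m
                 else NA_real_,
                 flagged = m == 0L, stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' Number of well-studied proteins per cutoff
#'
#' @param levels A `study_levels` object.
#' @param cutoffs Vector of cutoffs.
#' @return Data frame with columns `cutoff`, `n_proteins`; non-increasing
#'   in `cutoff`.
#' @export
well_studied_count_curve <- function(levels, cutoffs) {
  data.frame(cutoff = cutoffs,
             n_proteins = vapply(cutoffs, function(cut)
               length(well_studied_set(levels, cut)), integer(1L)))
}

#' Evidence-code enrichment in the well-studied LC subset
#'
#' Compares, per evidence code, the fraction of interactions carrying that
#' code in the full curated set versus its well-studied restriction. An
#' interaction counts once per code regardless of how many of its papers
#' used the assay. The p-value is a two-sided two-proportion chi-square
#' test, by default without continuity correction.
#'
#' @param lc Full curated `interaction_dataset`.
#' @param lc_ws Its well-studied restriction.
#' @param codes Evidence codes of interest; default every code seen in `lc`.
#' @param correct Apply Yates continuity correction; default `FALSE`.
#' @return Data frame with columns `code`, `prop_all`, `prop_ws`, `delta`
#'   (`prop_ws - prop_all`), `p_value`.
#' @export
evidence_code_enrichment <- function(lc, lc_ws,
                                     codes = sort(unique(unlist(lc$evidence))),
                                     correct = FALSE) {
  if (ds_size(lc) == 0L || ds_size(lc_ws) == 0L) {
    stop("evidence enrichment needs non-empty datasets")
  }
  n_all <- ds_size(lc)
  n_ws <- ds_size(lc_ws)
  rows <- lapply(codes, function(code) {
    k_all <- sum(vapply(lc$evidence, function(e) code %in% e, logical(1L)))
    k_ws <- sum(vapply(lc_ws$evidence, function(e) code %in% e, logical(1L)))
    p <- if (k_all %in% c(0L, n_all) && k_ws %in% c(0L, n_ws) &&
             k_all / n_all == k_ws / n_ws) {
      1
    } else {
      suppressWarnings(stats::prop.test(c(k_ws, k_all), c(n_ws, n_all),
                                        correct = correct)$p.value)
    }
    data.frame(code = code, prop_all = k_all / n_all, prop_ws = k_ws / n_ws,
               delta = k_ws / n_ws - k_all / n_all, p_value = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Well-studied proportions among recurated false and true positives
#'
#' From a recuration score table (0 = no confidence, 1 = unsubstantiated,
#' 2 = substantiated), takes score-0 pairs as false positives and score-2
#' pairs as true positives (score 1 is ignored) and reports the fraction of
#' each class whose pair involves a well-studied protein. Similar fractions
#' in both classes indicate the curated false-positive rate does not depend
#' on the level of study.
#'
#' @param scores Data frame from [load_recuration_scores()] (columns
#'   `protein_a`, `protein_b`, `score`).
#' @param ws Character vector of well-studied protein ids.
#' @param mode `"any"` (default) or `"both"` endpoints well-studied.
#' @return List with `fp_ws_fraction`, `tp_ws_fraction`, `n_fp`, `n_tp`.
#'   An empty class yields `NaN` for its fraction with a warning.
#' @export
recuration_ws_proportions <- function(scores, ws, mode = c("any", "both")) {
  mode <- match.arg(mode)
  stopifnot(all(scores$score %in% 0:2))
  ws <- toupper(ws)
  in_a <- toupper(scores$protein_a) %in% ws
  in_b <- toupper(scores$protein_b) %in% ws
  involves <- if (mode == "any") in_a | in_b else in_a & in_b
  frac <- function(class_rows) {
    if (!any(class_rows)) {
      warning("empty recuration class; fraction undefined")
      return(NaN)
    }
    mean(involves[class_rows])
  }
  list(fp_ws_fraction = frac(scores$score == 0L),
       tp_ws_fraction = frac(scores$score == 2L),
       n_fp = sum(scores$score == 0L),
       n_tp = sum(scores$score == 2L))
}
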