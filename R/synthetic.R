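#' Generate a synthetic interactome world
#'
#' Builds a ground-truth interactome with the statistical structure the
#' overlap method assumes about real data: degree heterogeneity (true
#' pairs drawn with heavy-tailed per-protein weights), study levels that
#' are rank-correlated with degree (well-connected proteins attract more
#' papers), and a per-interaction detectability score in (0, 1] standing in
#' for how easily a widespread assay (e.g. Y2H) finds the interaction.
#'
#' @param n_proteins Number of proteins.
#' @param n_true Number of genuine interactions (must be feasible for
#'   `n_proteins`; self-pairs are allowed).
#' @param degree_concentration Log-normal sdlog of the per-protein sampling
#'   weights; 0 gives homogeneous degrees, larger values heavier tails.
#'   Default 1.
#' @param study_degree_correlation Target rank correlation between a
#'   protein's degree and its paper count, achieved through a Gaussian
#'   copula; default 0.6.
#' @param detectability_shape Length-2 beta shape parameters for the
#'   per-pair detectability distribution; default `c(1, 1)` (uniform).
#' @param study_meanlog,study_sdlog Log-normal marginal of paper counts;
#'   defaults 3 and 1.2 put roughly 6\% of proteins above the conventional
#'   well-studied cutoff of 125 papers.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return An object of class `synthetic_world`: list with `proteins`,
#'   `pair_a`, `pair_b`, `key`, `detectability`, `degree`, `study_levels`,
#'   `n_true`, `params`.
#' @export
generate_world <- function(n_proteins = 2000, n_true = 5000,
                           degree_concentration = 1,
                           study_degree_correlation = 0.6,
                           detectability_shape = c(1, 1),
                           study_meanlog = 3, study_sdlog = 1.2,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  max_pairs <- n_proteins * (n_proteins + 1) / 2
  if (n_true > max_pairs) {
    stop("n_true exceeds the number of possible pairs for ", n_proteins,
         " proteins")
  }
  stopifnot(study_degree_correlation >= -1, study_degree_correlation <= 1)
  proteins <- sprintf("P%05d", seq_len(n_proteins))
  w <- if (degree_concentration > 0) {
    stats::rlnorm(n_proteins, 0, degree_concentration)
  } else {
    rep(1, n_proteins)
  }
  # rejection-free batched sampling of distinct weighted pairs
  a_idx <- integer(0)
  b_idx <- integer(0)
  keys <- character(0)
  while (length(keys) < n_true) {
    m <- max(2L * (n_true - length(keys)), 1000L)
    ai <- sample.int(n_proteins, m, replace = TRUE, prob = w)
    bi <- sample.int(n_proteins, m, replace = TRUE, prob = w)
    lo <- pmin(ai, bi)
    hi <- pmax(ai, bi)
    k <- paste(lo, hi, sep = "_")
    new <- !duplicated(k) & !(k %in% keys)
    take <- which(new)[seq_len(min(sum(new), n_true - length(keys)))]
    a_idx <- c(a_idx, lo[take])
    b_idx <- c(b_idx, hi[take])
    keys <- c(keys, k[take])
  }
  degree <- tabulate(c(a_idx, b_idx), nbins = n_proteins)
  rho <- study_degree_correlation
  # Gaussian copula: normal scores of (jittered) degree ranks, mixed with
  # independent noise, mapped through a log-normal marginal
  z_deg <- stats::qnorm((rank(degree, ties.method = "random") - 0.5) / n_proteins)
  s <- rho * z_deg + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n_proteins)
  papers <- pmax(0L, as.integer(round(stats::qlnorm(stats::pnorm(s),
                                                    study_meanlog, study_sdlog))))
  det <- pmin(1, pmax(0.02, stats::rbeta(n_true, detectability_shape[1L],
                                         detectability_shape[2L])))
  structure(list(
    proteins = proteins,
    pair_a = proteins[a_idx],
    pair_b = proteins[b_idx],
    key = paste(proteins[a_idx], proteins[b_idx], sep = "|"),
    detectability = det,
    degree = stats::setNames(degree, proteins),
    study_levels = study_levels(stats::setNames(papers, proteins)),
    n_true = n_true,
    params = list(n_proteins = n_proteins, n_true = n_true,
                  degree_concentration = degree_concentration,
                  study_degree_correlation = study_degree_correlation,
                  detectability_shape = detectability_shape,
                  study_meanlog = study_meanlog, study_sdlog = study_sdlog,
                  seed = seed)
  ), class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("Synthetic interactome world\n",
      sprintf("  proteins: %d, true interactions: %d\n",
              length(x$proteins), x$n_true),
      sprintf("  well-studied (>= 125 papers): %d\n",
              length(well_studied_set(x$study_levels, 125))))
  invisible(x)
}

.sample_false_pairs <- function(world, n_fp) {
  np <- length(world$proteins)
  a <- character(0)
  b <- character(0)
  keys <- character(0)
  while (length(keys) < n_fp) {
    m <- max(2L * (n_fp - length(keys)), 100L)
    ai <- sample.int(np, m, replace = TRUE)
    bi <- sample.int(np, m, replace = TRUE)
    lo <- pmin(ai, bi)
    hi <- pmax(ai, bi)
    k <- paste(world$proteins[lo], world$proteins[hi], sep = "|")
    ok <- !duplicated(k) & !(k %in% world$key) & !(k %in% keys)
    take <- which(ok)[seq_len(min(sum(ok), n_fp - length(keys)))]
    a <- c(a, world$proteins[lo[take]])
    b <- c(b, world$proteins[hi[take]])
    keys <- c(keys, k[take])
  }
  list(a = a, b = b)
}

#' Sample a high-throughput dataset from a synthetic world
#'
#' Each true interaction is captured independently with probability
#' proportional to `capture_prob * detectability^assay_exponent`
#' (normalised so the expected captured fraction is `capture_prob`);
#' `assay_exponent = 0` gives an assay-agnostic screen. False positives —
#' uniformly random pairs outside the ground truth — are then added so the
#' realised FDR matches `target_fdr`. Captured true pairs carry a pseudo-IST
#' hit count increasing with detectability, mimicking an
#' interaction-sequence-tag readout.
#'
#' @param world A `synthetic_world`.
#' @param capture_prob Expected fraction of true interactions captured.
#' @param assay_exponent Power of detectability in the capture weight;
#'   default 1.
#' @param target_fdr Target false-discovery rate in `[0, 1)`; default 0.
#' @param name Dataset label.
#' @param seed Optional integer seed.
#' @return An `interaction_dataset` with attributes `true_fdr` (realised
#'   FDR), `n_true_positives` and `n_false_positives` for oracle use.
#' @export
sample_ht_dataset <- function(world, capture_prob = 0.15, assay_exponent = 1,
                              target_fdr = 0, name = "HT-synth", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (target_fdr >= 1 || target_fdr < 0) stop("target_fdr must be in [0, 1)")
  wgt <- world$detectability^assay_exponent
  p <- pmin(1, capture_prob * wgt / mean(wgt))
  keep <- stats::runif(world$n_true) < p
  n_tp <- sum(keep)
  if (n_tp == 0L) stop("no true interaction captured; raise capture_prob")
  a <- world$pair_a[keep]
  b <- world$pair_b[keep]
  ist <- 1L + stats::rpois(n_tp, 8 * world$detectability[keep])
  n_fp <- round(n_tp * target_fdr / (1 - target_fdr))
  if (n_fp > 0) {
    fp <- .sample_false_pairs(world, n_fp)
    a <- c(a, fp$a)
    b <- c(b, fp$b)
    ist <- c(ist, 1L + stats::rpois(n_fp, 0.5))
  }
  ds <- interaction_dataset(a, b, name = name, ist_count = ist)
  attr(ds, "true_fdr") <- n_fp / (n_tp + n_fp)
  attr(ds, "n_true_positives") <- n_tp
  attr(ds, "n_false_positives") <- n_fp
  ds
}

#' Sample a literature-curated dataset from a synthetic world
#'
#' Models study-driven curation: the capture probability of a true pair is
#' proportional to
#' `detectability^e * ((papers_a + papers_b)/2 + 1)^study_bias`, normalised
#' to make the expected captured fraction `capture_prob`. The detectability
#' exponent `e` equals `detectability_bias` for ordinary pairs; when
#' `ws_assay_agnostic` is `TRUE` it is scaled by the fraction of endpoints
#' below the well-studied cutoff (0 for pairs with both endpoints
#' well-studied, 0.5 for mixed pairs) — encoding that well-studied proteins
#' have been probed with labor-intensive assays whose coverage does not
#' depend on routine-assay detectability. Publication counts, years
#' (a configurable fraction predating 2000) and evidence codes (Y2H more
#' likely for detectable pairs) are synthesised per record; false positives
#' are injected among single-paper records at `fp_rate`.
#'
#' @param world A `synthetic_world`.
#' @param capture_prob Expected fraction of true interactions captured.
#' @param detectability_bias Detectability exponent for ordinary pairs;
#'   0 = unbiased. Default 0.
#' @param study_bias Study-level exponent; 0 = unbiased. Default 0.
#' @param ws_assay_agnostic Scale the detectability exponent by the
#'   fraction of non-well-studied endpoints; default `FALSE`.
#' @param ws_cutoff Well-studied cutoff used by `ws_assay_agnostic`;
#'   default 125.
#' @param fp_rate Fraction of single-paper records that are false
#'   positives; default 0.
#' @param pre2000_fraction Fraction of synthetic publication years drawn
#'   before 2000; default 0.7.
#' @param mean_extra_pubs Poisson mean of additional supporting papers per
#'   record (so most records are single-paper); default 0.3.
#' @param name Dataset label.
#' @param seed Optional integer seed.
#' @return An `interaction_dataset` with publications, years and evidence
#'   codes, plus attributes `n_true_positives` and `n_false_positives`.
#' @export
sample_lc_dataset <- function(world, capture_prob = 0.3,
                              detectability_bias = 0, study_bias = 0,
                              ws_assay_agnostic = FALSE, ws_cutoff = 125,
                              fp_rate = 0, pre2000_fraction = 0.7,
                              mean_extra_pubs = 0.3, name = "LC-synth",
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(fp_rate >= 0, fp_rate < 1)
  det <- world$detectability
  expo <- rep(detectability_bias, world$n_true)
  if (ws_assay_agnostic && detectability_bias != 0) {
    ws <- well_studied_set(world$study_levels, ws_cutoff)
    frac_non_ws <- ((!(world$pair_a %in% ws)) + (!(world$pair_b %in% ws))) / 2
    expo <- detectability_bias * frac_non_ws
  }
  sl_a <- study_level_of(world$study_levels, world$pair_a)
  sl_b <- study_level_of(world$study_levels, world$pair_b)
  wgt <- det^expo * ((sl_a + sl_b) / 2 + 1)^study_bias
  p <- pmin(1, capture_prob * wgt / mean(wgt))
  keep <- stats::runif(world$n_true) < p
  n_tp <- sum(keep)
  if (n_tp == 0L) stop("no true interaction captured; raise capture_prob")
  a <- world$pair_a[keep]
  b <- world$pair_b[keep]
  det_kept <- det[keep]
  n_pubs <- 1L + stats::rpois(n_tp, mean_extra_pubs)
  n_single_tp <- sum(n_pubs == 1L)
  n_fp <- if (fp_rate > 0) round(fp_rate / (1 - fp_rate) * n_single_tp) else 0L
  if (n_fp > 0) {
    fp <- .sample_false_pairs(world, n_fp)
    a <- c(a, fp$a)
    b <- c(b, fp$b)
    det_kept <- c(det_kept, stats::rbeta(n_fp, 1, 1))
    n_pubs <- c(n_pubs, rep(1L, n_fp))
  }
  n_rec <- length(a)
  draw_year <- function(n) {
    pre <- stats::runif(n) < pre2000_fraction
    ifelse(pre, sample(1985:1999, n, replace = TRUE),
           sample(2000:2009, n, replace = TRUE))
  }
  pub_counter <- 0L
  pub_ids <- vector("list", n_rec)
  pub_years <- vector("list", n_rec)
  for (i in seq_len(n_rec)) {
    ids <- sprintf("SP%07d", pub_counter + seq_len(n_pubs[i]))
    pub_counter <- pub_counter + n_pubs[i]
    pub_ids[[i]] <- ids
    pub_years[[i]] <- as.integer(draw_year(n_pubs[i]))
  }
  other_codes <- c("Biochemical Activity", "Reconstituted Complex",
                   "Co-crystal Structure", "Far Western")
  ev <- lapply(seq_len(n_rec), function(i) {
    if (stats::runif(1) < det_kept[i]) "Two-hybrid"
    else sample(other_codes, 1L)
  })
  ds <- interaction_dataset(a, b, name = name, evidence_codes = ev,
                            pub_ids = pub_ids, pub_years = pub_years)
  attr(ds, "n_true_positives") <- n_tp
  attr(ds, "n_false_positives") <- n_fp
  ds
}

#' Export a synthetic world and its samples in the real input dialects
#'
#' Writes an LC sample as a BioGRID-style tab file, the world's study
#' levels as a gene-literature association table, HT samples as edge-list
#' TSVs (with a pseudo-IST column where present), and a ground-truth
#' manifest — so the complete loading pipeline can be exercised end-to-end
#' on files with known truth.
#'
#' @param world A `synthetic_world`.
#' @param lc LC `interaction_dataset` sampled from `world`.
#' @param ht_list Named list of HT `interaction_dataset`s sampled from
#'   `world`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named list of the written paths (`biogrid`,
#'   `study_levels`, one per HT dataset, `manifest`).
#' @export
export_world <- function(world, lc, ht_list, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  paths$biogrid <- file.path(dir, "interactions.tab")
  write_biogrid_tab(lc, paths$biogrid)
  paths$study_levels <- file.path(dir, "gene_literature.tsv")
  write_study_levels(world$study_levels, paths$study_levels)
  for (nm in names(ht_list)) {
    p <- file.path(dir, paste0(gsub("[^A-Za-z0-9_-]", "_", nm), ".tsv"))
    write_edge_list(ht_list[[nm]], p)
    paths[[nm]] <- p
  }
  paths$manifest <- file.path(dir, "manifest.yml")
  yaml::write_yaml(list(n_true = world$n_true,
                        n_proteins = length(world$proteins),
                        params = world$params), paths$manifest)
  invisible(paths)
}

#' Write an interaction dataset as a BioGRID-dialect tab file
#'
#' One row per (pair, publication) with the legacy column layout the
#' loader consumes (`INTERACTOR_A`, `INTERACTOR_B`, `EXPERIMENTAL_SYSTEM`,
#' `SOURCE` with an embedded year, `PUBMED_ID`).
#'
#' @param ds An `interaction_dataset` with publications.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_biogrid_tab <- function(ds, path) {
  n <- ds_size(ds)
  rows <- lapply(seq_len(n), function(i) {
    pubs <- ds$pub_ids[[i]]
    yrs <- ds$pub_years[[i]]
    if (length(pubs) == 0L) {
      pubs <- sprintf("NOPUB%06d", i)
      yrs <- NA_integer_
    }
    ev <- ds$evidence[[i]]
    if (length(ev) == 0L) ev <- "Two-hybrid"
    data.frame(
      INTERACTOR_A = ds$pairs$a[i], INTERACTOR_B = ds$pairs$b[i],
      EXPERIMENTAL_SYSTEM = rep_len(ev, length(pubs)),
      SOURCE = ifelse(is.na(yrs), "Synthetic AB",
                      sprintf("Synthetic AB (%d)", yrs)),
      PUBMED_ID = pubs, stringsAsFactors = FALSE
    )
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write study levels as a gene-literature association table
#'
#' Expands each protein's paper count into distinct synthetic paper ids,
#' one (gene, paper) row each — the dialect [load_study_levels()] reads.
#'
#' @param levels A `study_levels` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_levels <- function(levels, path) {
  counts <- unclass(levels)
  gene <- rep(names(counts), counts)
  paper <- unlist(lapply(seq_along(counts), function(i) {
    if (counts[i] == 0L) character(0)
    else sprintf("%s_P%04d", names(counts)[i], seq_len(counts[i]))
  }))
  utils::write.table(data.frame(gene = gene, paper = paper),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an interaction dataset as an edge-list TSV
#'
#' Two id columns plus an IST-count column when the dataset carries IST
#' annotations.
#'
#' @param ds An `interaction_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(ds, path) {
  df <- ds$pairs[, c("a", "b")]
  if (!all(is.na(ds$ist))) df$ist <- ds$ist
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
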