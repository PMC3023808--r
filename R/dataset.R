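#' Interaction dataset
#'
#' Container for a named set of canonical protein pairs with per-pair
#' metadata: supporting publications (ids and years), experimental evidence
#' codes, and optional IST (interaction sequence tag) hit counts. Rows with
#' the same canonical pair are merged on construction: evidence codes and
#' publications are unioned, IST counts summed. Dataset size always counts
#' distinct pairs, never input rows.
#'
#' @param protein_a,protein_b Character vectors of interactor identifiers.
#' @param name Dataset label (e.g. `"Uetz-Screen"`).
#' @param evidence_codes Optional list of character vectors (one per row) or
#'   a single character vector recycled per row.
#' @param pub_ids Optional list of character vectors of publication ids, or
#'   a character vector (one id per row).
#' @param pub_years Optional list of integer vectors aligned with `pub_ids`,
#'   or an integer vector (one year per row).
#' @param ist_count Optional non-negative integer vector of IST hits per row.
#' @return An object of class `interaction_dataset`.
#' @export
interaction_dataset <- function(protein_a, protein_b, name = "",
                                evidence_codes = NULL, pub_ids = NULL,
                                pub_years = NULL, ist_count = NULL) {
  n <- length(protein_a)
  if (n == 0L) {
    return(empty_dataset(name))
  }
  cp <- canonical_pair(protein_a, protein_b)
  key <- paste(cp[, 1L], cp[, 2L], sep = "|")

  as_row_list <- function(x, coerce) {
    if (is.null(x)) return(rep(list(coerce(character(0))), n))
    if (is.list(x)) return(lapply(rep_len(x, n), coerce))
    lapply(rep_len(x, n), function(v) coerce(v[!is.na(v)]))
  }
  ev <- as_row_list(evidence_codes, as.character)
  pid <- as_row_list(pub_ids, as.character)
  pyr <- as_row_list(pub_years, as.integer)
  ist <- if (is.null(ist_count)) rep(NA_real_, n) else rep_len(as.numeric(ist_count), n)
  if (any(!is.na(ist) & ist < 0)) stop("ist_count must be non-negative")

  # merge duplicate rows per canonical pair
  idx <- split(seq_len(n), key)
  keys <- names(idx)
  a <- b <- character(length(idx))
  merged_ev <- merged_pid <- merged_pyr <- vector("list", length(idx))
  merged_ist <- numeric(length(idx))
  for (i in seq_along(idx)) {
    rows <- idx[[i]]
    a[i] <- cp[rows[1L], 1L]
    b[i] <- cp[rows[1L], 2L]
    merged_ev[[i]] <- sort(unique(unlist(ev[rows])))
    pubs <- unlist(pid[rows])
    yrs <- unlist(pyr[rows])
    if (length(yrs) < length(pubs)) yrs <- c(yrs, rep(NA_integer_, length(pubs) - length(yrs)))
    keep <- !duplicated(pubs)
    merged_pid[[i]] <- pubs[keep]
    merged_pyr[[i]] <- as.integer(yrs[keep])
    v <- ist[rows]
    merged_ist[i] <- if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
  }
  ord <- order(keys)
  structure(list(
    name = name,
    pairs = data.frame(a = a[ord], b = b[ord], key = keys[ord],
                       stringsAsFactors = FALSE),
    evidence = merged_ev[ord],
    pub_ids = merged_pid[ord],
    pub_years = merged_pyr[ord],
    ist = merged_ist[ord]
  ), class = "interaction_dataset")
}

empty_dataset <- function(name = "") {
  structure(list(
    name = name,
    pairs = data.frame(a = character(0), b = character(0), key = character(0),
                       stringsAsFactors = FALSE),
    evidence = list(), pub_ids = list(), pub_years = list(), ist = numeric(0)
  ), class = "interaction_dataset")
}

#' @export
print.interaction_dataset <- function(x, ...) {
  cat("Interaction dataset", if (nzchar(x$name)) sQuote(x$name) else "",
      "\n  pairs:", ds_size(x),
      "\n  proteins:", length(unique(c(x$pairs$a, x$pairs$b))), "\n")
  invisible(x)
}

#' @export
length.interaction_dataset <- function(x) nrow(x$pairs)

#' Number of distinct pairs in a dataset
#' @param ds An `interaction_dataset`.
#' @return Integer count of distinct canonical pairs.
#' @export
ds_size <- function(ds) nrow(ds$pairs)

#' Canonical pair keys of a dataset
#' @param ds An `interaction_dataset`.
#' @return Character vector of `"A|B"` keys.
#' @export
ds_keys <- function(ds) ds$pairs$key

subset_dataset <- function(ds, keep, name = ds$name) {
  structure(list(
    name = name,
    pairs = ds$pairs[keep, , drop = FALSE],
    evidence = ds$evidence[keep],
    pub_ids = ds$pub_ids[keep],
    pub_years = ds$pub_years[keep],
    ist = ds$ist[keep]
  ), class = "interaction_dataset")
}

#' Intersection of two interaction datasets
#'
#' Set intersection on canonical pairs; metadata is taken from the first
#' dataset.
#'
#' @param ds1,ds2 `interaction_dataset` objects.
#' @param name Label for the result.
#' @return An `interaction_dataset` with the pairs present in both inputs.
#' @export
intersect_datasets <- function(ds1, ds2,
                               name = paste(ds1$name, ds2$name, sep = " & ")) {
  subset_dataset(ds1, ds1$pairs$key %in% ds2$pairs$key, name = name)
}

#' Union of interaction datasets
#'
#' Set union on canonical pairs. Metadata for pairs present in several
#' inputs is merged (evidence and publications unioned, IST counts summed
#' where present).
#'
#' @param ... `interaction_dataset` objects, or a single list of them.
#' @param name Label for the result.
#' @return An `interaction_dataset`.
#' @export
union_datasets <- function(..., name = "union") {
  dss <- list(...)
  if (length(dss) == 1L && !inherits(dss[[1L]], "interaction_dataset")) {
    dss <- dss[[1L]]
  }
  dss <- Filter(function(d) ds_size(d) > 0L, dss)
  if (length(dss) == 0L) return(empty_dataset(name))
  interaction_dataset(
    protein_a = unlist(lapply(dss, function(d) d$pairs$a)),
    protein_b = unlist(lapply(dss, function(d) d$pairs$b)),
    name = name,
    evidence_codes = do.call(c, lapply(dss, function(d) d$evidence)),
    pub_ids = do.call(c, lapply(dss, function(d) d$pub_ids)),
    pub_years = do.call(c, lapply(dss, function(d) d$pub_years)),
    ist_count = unlist(lapply(dss, function(d) d$ist))
  )
}

#' Restrict a dataset to interactions reported before a given year
#'
#' Keeps pairs with at least one supporting publication strictly older than
#' `year`. Retained records keep their full metadata.
#'
#' @param ds An `interaction_dataset`.
#' @param year Cutoff year; default 2000, the publication year of the oldest
#'   genome-scale screen, so that low-throughput confirmations of
#'   high-throughput hits cannot inflate dataset overlap.
#' @return An `interaction_dataset`.
#' @export
restrict_before_year <- function(ds, year = 2000) {
  keep <- vapply(ds$pub_years, function(y) any(!is.na(y) & y < year), logical(1L))
  subset_dataset(ds, keep, name = paste0(ds$name, "-pre", year))
}

#' Restrict a dataset to interactions involving well-studied proteins
#'
#' @param ds An `interaction_dataset`.
#' @param ws Character vector of well-studied protein ids (see
#'   [well_studied_set()]).
#' @param mode `"any"` (default) keeps pairs with at least one endpoint in
#'   `ws`; `"both"` requires both endpoints.
#' @return An `interaction_dataset`.
#' @export
restrict_well_studied <- function(ds, ws, mode = c("any", "both")) {
  mode <- match.arg(mode)
  ws <- toupper(ws)
  in_a <- ds$pairs$a %in% ws
  in_b <- ds$pairs$b %in% ws
  keep <- if (mode == "any") in_a | in_b else in_a & in_b
  subset_dataset(ds, keep, name = paste0(ds$name, "-WS"))
}

#' Single-paper interactions absent from an HT dataset
#'
#' The subset of `lc` supported by exactly one publication and whose pair is
#' not present in `ht`. Under the recuration-based error model these are the
#' interactions carrying the literature-curation false-positive rate.
#'
#' @param lc Literature-curated `interaction_dataset`.
#' @param ht High-throughput `interaction_dataset` under consideration.
#' @return An `interaction_dataset`.
#' @export
single_paper_unique <- function(lc, ht) {
  n_pubs <- vapply(lc$pub_ids, function(p) length(unique(p)), integer(1L))
  keep <- n_pubs == 1L & !(lc$pairs$key %in% ht$pairs$key)
  subset_dataset(lc, keep, name = paste0(lc$name, "-Unique"))
}
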