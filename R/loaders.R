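#' Default evidence-code whitelist for binary physical interactions
#'
#' The BioGRID "Experimental System" values accepted as direct binary
#' physical evidence. "PCA" additionally matches the spelled-out
#' "Protein-fragment Complementation Assay" used by some BioGRID releases.
#' @export
BINARY_PHYSICAL_CODES <- c(
  "Reconstituted Complex", "Two-hybrid", "Far Western",
  "Biochemical Activity", "Co-crystal Structure", "Protein-peptide",
  "PCA", "FRET"
)

.default_column_map <- list(
  a = "INTERACTOR_A", b = "INTERACTOR_B",
  system = "EXPERIMENTAL_SYSTEM", pub = "PUBMED_ID",
  source = "SOURCE", year = NULL,
  organism_a = "ORGANISM_A_ID", organism_b = "ORGANISM_B_ID"
)

#' Load a BioGRID organism tab-delimited interaction file
#'
#' Reads the legacy BioGRID `.tab` dialect (one row per reported interaction
#' with interactor ids, experimental system, source and PubMed id). A column
#' map adapts the loader to Tab 2.0/3.0 layouts. Publication year is taken
#' from a dedicated year column when `column_map$year` is set, otherwise
#' parsed from a `"Author AB (1999)"`-style source column.
#'
#' @param path Path to the tab-delimited file. Lines starting with `#` are
#'   treated as comments.
#' @param organism_filter Optional organism id; when given and organism
#'   columns are present, rows where either interactor belongs to a
#'   different organism are dropped.
#' @param column_map Named list overriding entries of the default map
#'   (`a`, `b`, `system`, `pub`, `source`, `year`, `organism_a`,
#'   `organism_b`).
#' @return A data frame of raw records with columns `protein_a`,
#'   `protein_b`, `key`, `evidence`, `pub_id`, `pub_year`. Malformed rows
#'   (missing interactor or empty id) are skipped with a warning giving the
#'   count.
#' @export
load_biogrid_tab <- function(path, organism_filter = NULL, column_map = list()) {
  if (!file.exists(path)) stop("cannot read BioGRID file: ", path)
  cm <- utils::modifyList(.default_column_map, column_map)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE)
  need <- c(cm$a, cm$b, cm$system, cm$pub)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("BioGRID file lacks expected columns: ",
         paste(missing_cols, collapse = ", "))
  }
  a <- as.character(raw[[cm$a]])
  b <- as.character(raw[[cm$b]])
  ok <- !is.na(a) & !is.na(b) & nzchar(trimws(a)) & nzchar(trimws(b)) &
    a != "-" & b != "-"
  if (any(!ok)) {
    warning(sum(!ok), " malformed row(s) skipped in ", basename(path))
  }
  if (!is.null(organism_filter) &&
      all(c(cm$organism_a, cm$organism_b) %in% names(raw))) {
    ok <- ok & raw[[cm$organism_a]] == organism_filter &
      raw[[cm$organism_b]] == organism_filter
  }
  raw <- raw[ok, , drop = FALSE]
  a <- trimws(a[ok]); b <- trimws(b[ok])
  year <- if (!is.null(cm$year) && cm$year %in% names(raw)) {
    suppressWarnings(as.integer(raw[[cm$year]]))
  } else if (cm$source %in% names(raw)) {
    m <- regmatches(raw[[cm$source]],
                    regexpr("\\((1[89][0-9]{2}|20[0-9]{2})\\)", raw[[cm$source]]))
    yr <- rep(NA_integer_, nrow(raw))
    has <- lengths(regmatches(raw[[cm$source]],
                   gregexpr("\\((1[89][0-9]{2}|20[0-9]{2})\\)", raw[[cm$source]]))) > 0
    yr[has] <- as.integer(gsub("[()]", "", m))
    yr
  } else {
    rep(NA_integer_, nrow(raw))
  }
  cp <- canonical_pair(a, b)
  data.frame(
    protein_a = cp[, 1L], protein_b = cp[, 2L],
    key = paste(cp[, 1L], cp[, 2L], sep = "|"),
    evidence = as.character(raw[[cm$system]]),
    pub_id = as.character(raw[[cm$pub]]),
    pub_year = year,
    stringsAsFactors = FALSE
  )
}

#' Classify publications as low- or high-throughput
#'
#' A publication is high-throughput when it supports strictly more distinct
#' canonical pairs than `ht_paper_threshold` in the loaded file. The
#' classification runs over the whole organism file before any
#' evidence-code filtering, so a genome-scale genetic screen still counts
#' against its paper.
#'
#' @param records Raw record data frame from [load_biogrid_tab()].
#' @param ht_paper_threshold Pair-count threshold; default 100 (a paper
#'   reporting more than 100 interactions is considered high-throughput).
#' @return Named character vector mapping publication id to `"low"` or
#'   `"high"`.
#' @export
classify_publication_throughput <- function(records, ht_paper_threshold = 100) {
  stopifnot(ht_paper_threshold >= 1)
  if (nrow(records) == 0L) return(stats::setNames(character(0), character(0)))
  n_pairs <- vapply(split(records$key, records$pub_id),
                    function(k) length(unique(k)), integer(1L))
  stats::setNames(ifelse(n_pairs > ht_paper_threshold, "high", "low"),
                  names(n_pairs))
}

#' Curate low-throughput binary physical interactions
#'
#' Applies the two curation filters in order: (1) drop rows supported by
#' high-throughput publications (more than `ht_paper_threshold` distinct
#' pairs in the file); (2) among the remaining rows keep those whose
#' experimental system is in the binary-physical whitelist. Surviving rows
#' are merged into one record per canonical pair with evidence codes and
#' publications unioned, so a pair supported by both a low- and a
#' high-throughput paper is retained with only its low-throughput
#' publication attached.
#'
#' @param records Raw record data frame from [load_biogrid_tab()].
#' @param evidence_whitelist Accepted evidence codes; default
#'   [BINARY_PHYSICAL_CODES]. Matching is exact but case-insensitive;
#'   `"PCA"` also matches `"Protein-fragment Complementation Assay"`.
#' @param ht_paper_threshold Passed to [classify_publication_throughput()].
#' @param keep_self_pairs Keep homodimers (default `TRUE`).
#' @param name Dataset label, default `"LowBP-LC"`.
#' @return An `interaction_dataset` of curated low-throughput binary
#'   physical interactions.
#' @export
filter_binary_physical_low_throughput <- function(records,
    evidence_whitelist = BINARY_PHYSICAL_CODES,
    ht_paper_threshold = 100, keep_self_pairs = TRUE, name = "LowBP-LC") {
  if (length(evidence_whitelist) == 0L) {
    stop("evidence whitelist must not be empty")
  }
  wl <- tolower(evidence_whitelist)
  if ("pca" %in% wl) {
    wl <- c(wl, "protein-fragment complementation assay")
  }
  cls <- classify_publication_throughput(records, ht_paper_threshold)
  keep <- cls[records$pub_id] == "low" &
    tolower(records$evidence) %in% wl
  if (!keep_self_pairs) keep <- keep & records$protein_a != records$protein_b
  rec <- records[keep, , drop = FALSE]
  interaction_dataset(
    rec$protein_a, rec$protein_b, name = name,
    evidence_codes = as.list(rec$evidence),
    pub_ids = rec$pub_id, pub_years = rec$pub_year
  )
}

#' Load protein study levels from a gene-literature association table
#'
#' Reads a two-column (gene, paper id) tab-delimited table in the style of
#' the Saccharomyces Genome Database gene-literature dump and counts the
#' number of distinct papers citing each gene. Proteins absent from the
#' table have an implicit study level of 0.
#'
#' @param path Path to the tab-delimited table. A header line is detected
#'   and skipped when its first field is not a systematic name-like token.
#' @return A named integer vector (class `study_levels`) mapping protein id
#'   to its number of citing papers.
#' @export
load_study_levels <- function(path) {
  if (!file.exists(path)) stop("cannot read study-level table: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!any(nzchar(lines) & !startsWith(lines, "#"))) {
    return(study_levels(integer(0)))
  }
  tab <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (tolower(tab[1L, 1L]) %in% c("gene", "orf", "systematic_name")) {
    tab <- tab[-1L, , drop = FALSE]
  }
  gene <- toupper(trimws(as.character(tab[[1L]])))
  paper <- as.character(tab[[2L]])
  ok <- nzchar(gene) & nzchar(paper)
  counts <- vapply(split(paper[ok], gene[ok]),
                   function(p) length(unique(p)), integer(1L))
  study_levels(counts)
}

#' Study levels constructor
#'
#' @param counts Named non-negative integer vector (protein -> number of
#'   citing papers).
#' @return A `study_levels` object. Lookup of an absent protein yields 0.
#' @export
study_levels <- function(counts) {
  ids <- names(counts)
  counts <- as.integer(counts)
  if (any(counts < 0, na.rm = TRUE)) stop("study levels must be >= 0")
  structure(counts, names = toupper(ids), class = "study_levels")
}

#' Look up study levels with an implicit zero default
#' @param levels A `study_levels` object.
#' @param proteins Character vector of protein ids.
#' @return Integer vector of paper counts (0 for unknown proteins).
#' @export
study_level_of <- function(levels, proteins) {
  v <- unclass(levels)[toupper(proteins)]
  v[is.na(v)] <- 0L
  unname(v)
}

#' Well-studied protein set
#'
#' Proteins cited in at least `cutoff` papers (inclusive boundary).
#'
#' @param levels A `study_levels` object.
#' @param cutoff Minimum number of referencing papers; default 125.
#' @return Character vector of protein ids.
#' @export
well_studied_set <- function(levels, cutoff = 125) {
  stopifnot(cutoff >= 1)
  names(levels)[unclass(levels) >= cutoff]
}

#' Load a plain edge-list TSV as an interaction dataset
#'
#' Two id columns, optional third IST-count column (used for Ito-Full-style
#' screens where each interaction carries an interaction-sequence-tag hit
#' count).
#'
#' @param path Path to the TSV file. Lines starting with `#` are comments;
#'   a header is detected when the third field of the first line is
#'   non-numeric.
#' @param name Dataset label.
#' @return An `interaction_dataset` (with `ist` populated when a third
#'   column is present).
#' @export
load_edge_list <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("cannot read edge list: ", path)
  tab <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) return(empty_dataset(name))
  first <- as.character(unlist(tab[1L, ]))
  looks_header <- tolower(first[1L]) %in% c("protein_a", "a", "interactor_a") ||
    (ncol(tab) >= 3L && is.na(suppressWarnings(as.numeric(first[3L]))) &&
       tolower(first[3L]) %in% c("ist", "ist_count", "hits"))
  if (looks_header) tab <- tab[-1L, , drop = FALSE]
  ist <- if (ncol(tab) >= 3L) suppressWarnings(as.numeric(tab[[3L]])) else NULL
  interaction_dataset(trimws(tab[[1L]]), trimws(tab[[2L]]), name = name,
                      ist_count = ist)
}

#' Load a recuration score table
#'
#' TSV with columns (protein_a, protein_b, score) where score is 0 (no
#' confidence), 1 (low confidence/unsubstantiated) or 2 (substantiated).
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `protein_a`, `protein_b`, `key`, `score`.
#' @export
load_recuration_scores <- function(path) {
  if (!file.exists(path)) stop("cannot read recuration table: ", path)
  tab <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (is.na(suppressWarnings(as.integer(tab[1L, 3L])))) {
    tab <- tab[-1L, , drop = FALSE]
  }
  score <- as.integer(tab[[3L]])
  if (any(!score %in% 0:2)) stop("recuration scores must be 0, 1 or 2")
  cp <- canonical_pair(trimws(tab[[1L]]), trimws(tab[[2L]]))
  data.frame(protein_a = cp[, 1L], protein_b = cp[, 2L],
             key = paste(cp[, 1L], cp[, 2L], sep = "|"),
             score = score, stringsAsFactors = FALSE)
}
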