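#' Normalize gene symbols
#'
#' Gene matching across tables is case-insensitive with whitespace stripped;
#' known typographical variants (e.g. Carl3/Calr3, R1f/Rlf, Rio1/Riok1,
#' Igbo-V7183/Igh-V7183) are mapped to canonical symbols through a packaged
#' alias table.
#'
#' @param genes Character vector of gene symbols.
#' @return Canonical lowercase symbols.
#' @export
normalize_gene <- function(genes) {
  x <- tolower(gsub("[[:space:]]+", "", genes))
  x <- gsub("‐|‑|–", "-", x)  # unicode hyphens
  al <- gene_alias_table()
  hit <- match(x, al$alias)
  x[!is.na(hit)] <- al$canonical[hit[!is.na(hit)]]
  x
}

gene_alias_table <- function() {
  path <- system.file("extdata", "gene_aliases.csv", package = "gliaquant")
  if (path == "") path <- file.path("inst", "extdata", "gene_aliases.csv")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Filter a gene fold table into up/down sets per group
#'
#' A gene is upregulated in a group when its signed fold is at least
#' `up_cut` and downregulated when at most `down_cut` (both inclusive, so a
#' fold of exactly 2.00 passes the default up cutoff). Downregulation is
#' stored as a negative mirrored fold (e.g. -2.69), not a ratio below 1.
#'
#' @param records Data frame with columns `gene`, `group`, `fold`.
#' @param up_cut Upregulation cutoff (>= 1; default 2).
#' @param down_cut Downregulation cutoff (<= -1; default -2).
#' @return List with `up` and `down`: each a named list (per group) of
#'   normalized gene symbol vectors.
#' @export
filter_by_fold <- function(records, up_cut = 2, down_cut = -2) {
  stopifnot(all(c("gene", "group", "fold") %in% names(records)))
  if (up_cut < 1 || down_cut > -1)
    stop("cutoffs must satisfy up_cut >= 1 and down_cut <= -1")
  records$gene <- normalize_gene(records$gene)
  groups <- unique(records$group)
  pick <- function(keep) {
    out <- lapply(groups, function(g)
      sort(unique(records$gene[keep & records$group == g])))
    names(out) <- groups
    out
  }
  list(up = pick(records$fold >= up_cut),
       down = pick(records$fold <= down_cut))
}

#' Exact Venn-region intersection of gene sets
#'
#' Assigns every element of the union to the exact subset of groups that
#' contain it, producing disjoint Venn regions whose counts sum to the size
#' of the union. Supports 2 to 4 groups (and degenerates gracefully above).
#'
#' @param sets Named list (>= 2 entries) of character vectors.
#' @return `VennResult`: list with `groups` (input order), `membership`
#'   (data frame `element`, `region`; elements sorted), and `region_counts`
#'   (named integer vector over nonempty regions). Region keys are group
#'   names joined by `&` in input order.
#' @export
intersect_sets <- function(sets) {
  if (length(sets) < 2) stop("need at least 2 groups")
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("'sets' must be a fully named list")
  groups <- names(sets)
  sets <- lapply(sets, unique)
  universe <- sort(unique(unlist(sets)))
  region <- vapply(universe, function(el) {
    paste(groups[vapply(sets, function(s) el %in% s, logical(1))],
          collapse = "&")
  }, character(1))
  counts <- table(region)
  structure(list(groups = groups,
                 membership = data.frame(element = universe, region = region,
                                         row.names = NULL),
                 region_counts = stats::setNames(as.integer(counts),
                                                 names(counts))),
            class = "VennResult")
}

#' Size of the intersection of selected groups
#'
#' Number of elements present in *all* of `groups` (regardless of
#' membership in other groups), computed from the disjoint Venn regions.
#'
#' @param venn A [intersect_sets()] result.
#' @param groups Character vector of group names.
#' @param exact If TRUE, count only the exact Venn region: elements
#'   belonging to these groups and to no others.
#' @return Integer count.
#' @export
intersection_size <- function(venn, groups, exact = FALSE) {
  stopifnot(inherits(venn, "VennResult"))
  member_groups <- strsplit(venn$membership$region, "&", fixed = TRUE)
  if (exact) {
    want <- sort(groups)
    sum(vapply(member_groups, function(g) identical(sort(g), want),
               logical(1)))
  } else {
    sum(vapply(member_groups, function(g) all(groups %in% g), logical(1)))
  }
}

#' Screen perturbagen entries by connectivity score
#'
#' Retains entries whose connectivity score strictly exceeds the threshold
#' ("exceeding 80.0" / "above 90.0" are strict inequalities) and tabulates
#' retained counts per group and kind.
#'
#' @param entries Data frame with columns `name`, `kind` (`"PCL"` or
#'   `"PC"`), `group`, `score` (in \[-100, 100\]).
#' @param threshold Score threshold in \[-100, 100\].
#' @param kind Optional filter on entry kind before screening.
#' @return List with `entries` (retained rows) and `counts` (data frame
#'   `group`, `kind`, `n`).
#' @export
filter_scores <- function(entries, threshold, kind = NULL) {
  stopifnot(all(c("name", "kind", "group", "score") %in% names(entries)))
  if (threshold < -100 || threshold > 100)
    stop("threshold must lie in [-100, 100]")
  if (any(entries$score < -100 | entries$score > 100))
    stop("scores must lie in [-100, 100]")
  if (!is.null(kind)) entries <- entries[entries$kind %in% kind, ]
  kept <- entries[entries$score > threshold, ]
  counts <- as.data.frame(table(group = kept$group, kind = kept$kind),
                          responseName = "n", stringsAsFactors = FALSE)
  counts <- counts[counts$n > 0 | TRUE, ]
  list(entries = kept, counts = counts)
}

#' Common-group annotation strings for shared elements
#'
#' For each element of a Venn result, renders the groups containing it
#' (optionally excluding a reference group, e.g. the untreated comparison
#' every table row already belongs to) as a comma-separated annotation such
#' as `"A1, S1, C1"`, in the group order of the Venn input.
#'
#' @param venn A [intersect_sets()] result.
#' @param exclude Groups to omit from the annotation (default none).
#' @return Data frame `element`, `common_group`.
#' @export
shared_annotations <- function(venn, exclude = character()) {
  stopifnot(inherits(venn, "VennResult"))
  ord <- setdiff(venn$groups, exclude)
  ann <- vapply(strsplit(venn$membership$region, "&", fixed = TRUE),
                function(g) paste(ord[ord %in% g], collapse = ", "),
                character(1))
  data.frame(element = venn$membership$element, common_group = ann,
             row.names = NULL)
}

#' Parse a common-group annotation string back into group names
#'
#' Inverse of the [shared_annotations()] format: `"A1, S1, C1"` becomes
#' `c("A1", "S1", "C1")`. Semicolon separators (used in the score table)
#' are accepted too; `NA` parses to no groups.
#'
#' @param x Character vector of annotation strings.
#' @return List of character vectors.
#' @export
parse_common_group <- function(x) {
  x[is.na(x)] <- ""
  lapply(strsplit(x, "[,;]"), function(p) {
    p <- trimws(p)
    p[p != ""]
  })
}

# --- packaged table fixtures -------------------------------------------------

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "gliaquant")
  if (p == "") p <- file.path("inst", "extdata", file)
  p
}

#' Packaged perturbagen-class score table
#'
#' Transcription of the published perturbagen-class (PCL) connectivity-score
#' screen for the four comparison groups (D4, A1, S1, C1), scores in
#' \[-100, 100\].
#'
#' @return Data frame `name`, `kind`, `group`, `score`, `common_group`.
#' @export
pcl_score_table <- function() {
  utils::read.csv(fixture_path("table1_pcl_scores.csv"),
                  stringsAsFactors = FALSE)
}

#' Packaged gene fold tables
#'
#' Transcriptions of the published commonly-upregulated (folds >= 2) and
#' commonly-downregulated (folds <= -2) gene tables shared between the
#' matured-microglia comparison (D4) and the erinacine-treated comparisons
#' (A1, S1, C1). Every row belongs to D4; `common_group` lists the treated
#' groups sharing the gene.
#'
#' @param direction `"up"` or `"down"`.
#' @return Data frame `gene`, `fold`, `common_group`.
#' @export
gene_fold_table <- function(direction = c("up", "down")) {
  direction <- match.arg(direction)
  f <- if (direction == "up") "table2_upregulated_genes.csv"
       else "table3_downregulated_genes.csv"
  utils::read.csv(fixture_path(f), stringsAsFactors = FALSE)
}

#' Build per-group gene sets from a packaged fold table
#'
#' Expands the `common_group` annotation into explicit per-group gene sets:
#' every row is a member of the reference comparison (`D4`) plus the groups
#' named in its annotation.
#'
#' @param table Data frame from [gene_fold_table()].
#' @param base_group Group every row belongs to (default `"D4"`).
#' @param all_groups Group universe and output order.
#' @return Named list of normalized gene symbol vectors.
#' @export
fold_table_sets <- function(table, base_group = "D4",
                            all_groups = c("D4", "A1", "S1", "C1")) {
  genes <- normalize_gene(table$gene)
  members <- parse_common_group(table$common_group)
  sets <- lapply(all_groups, function(g) {
    if (g == base_group) return(sort(genes))
    sort(genes[vapply(members, function(m) g %in% m, logical(1))])
  })
  stats::setNames(sets, all_groups)
}
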