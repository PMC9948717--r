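#' Community count table
#'
#' Constructs a validated site x taxon count matrix for one cruise. Rows are
#' sampling sites, columns are taxa (ASVs); cells are non-negative integer
#' read counts.
#'
#' @param counts numeric matrix, sites in rows, taxa in columns; all cells
#'   must be non-negative integers. Row and column names are required.
#' @param cruise_id single string identifying the cruise.
#' @return A matrix of class `community_table` with a `cruise_id` attribute.
#' @export
community_table <- function(counts, cruise_id) {
  stopifnot(is.matrix(counts))
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have site row names and taxon column names")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("site and taxon names must be unique")
  if (!is.character(cruise_id) || length(cruise_id) != 1L)
    stop("cruise_id must be a single string")
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be finite non-negative integers")
  storage.mode(counts) <- "integer"
  structure(counts, cruise_id = cruise_id, class = c("community_table", "matrix"))
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("Community table: cruise %s, %d sites x %d taxa, depth range [%d, %d]\n",
              attr(x, "cruise_id"), nrow(x), ncol(x),
              min(rowSums(x)), max(rowSums(x))))
  invisible(x)
}

#' Cruise id of a community table
#' @param table a `community_table`.
#' @return The cruise id string.
#' @export
cruise_id <- function(table) attr(table, "cruise_id")

# internal: structural checks shared by read_phylogeny and the simulator
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylogenetic tree")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and >= 0")
  invisible(tree)
}

#' Read a rooted phylogeny from a newick file
#'
#' Parses a newick tree and validates the invariants the downstream
#' phylogenetic statistics rely on: unique tip labels and finite,
#' non-negative branch lengths (zero-length edges are allowed, as produced
#' by maximum-likelihood tree builders that clamp negative edges to 0).
#'
#' @param path path to a newick file.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_phylogeny <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  # pre-scan parentheses so a malformed file reports where it breaks
  depth <- 0L
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      stop(sprintf("newick parse error: unbalanced ')' at byte offset %d", i))
  }
  if (depth != 0L)
    stop(sprintf("newick parse error: %d unclosed '(' at byte offset %d",
                 depth, length(chars)))
  if (!grepl(";", txt, fixed = TRUE))
    stop(sprintf("newick parse error: missing ';' terminator at byte offset %d",
                 length(chars)))
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop("newick parse error: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("newick parse error: no tree in file")
  validate_phylogeny(tree)
}

#' Write a phylogeny to newick
#' @param tree a `phylo` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylogeny <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Read a community count table from TSV
#'
#' Expects a tab-separated file with a header row: first column `site`,
#' remaining columns one per taxon; cells are integer read counts.
#'
#' @param path path to the TSV file.
#' @param cruise single string; cruise id to attach to the table.
#' @return A `community_table`.
#' @export
read_counts <- function(path, cruise) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L || names(df)[1] != "site")
    stop("counts TSV must have a 'site' first column and >= 1 taxon column")
  sites <- df[[1]]
  num <- suppressWarnings(
    vapply(df[-1], function(col) as.numeric(col), numeric(nrow(df))))
  num <- matrix(num, nrow = nrow(df),
                dimnames = list(sites, names(df)[-1]))
  bad <- which(!is.finite(num) | num < 0 | abs(num - round(num)) > 1e-8,
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-integer or negative count at site '%s', taxon '%s'",
                 rownames(num)[bad[1, 1]], colnames(num)[bad[1, 2]]))
  community_table(num, cruise_id = cruise)
}

#' Write a community table to TSV
#' @param table a `community_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(table, path) {
  df <- data.frame(site = rownames(table), as.data.frame(unclass(table)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.metadata_cols <- c("cruise", "site", "biomass_ugC_L", "hnf_biomass_ugC_L",
                    "temperature", "salinity", "nitrogen", "phosphate",
                    "par", "chla")

#' Read per-site metadata from TSV
#'
#' The metadata table carries, per cruise-site, the bacterial community
#' biomass (ug C/L), HNF biomass (ug C/L) and the environmental covariates
#' used in the regression stages. Missing covariates are encoded as `NA`
#' and propagated; biomass must be positive wherever present.
#'
#' @param path path to the TSV file.
#' @return A `data.frame` with columns `cruise`, `site`, `biomass_ugC_L`,
#'   `hnf_biomass_ugC_L`, `temperature`, `salinity`, `nitrogen`,
#'   `phosphate`, `par`, `chla`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          na.strings = "NA", check.names = FALSE)
  missing_cols <- setdiff(.metadata_cols, names(df))
  if (length(missing_cols) > 0)
    stop("metadata missing columns: ", paste(missing_cols, collapse = ", "))
  df$cruise <- as.character(df$cruise)
  df$site <- as.character(df$site)
  if (anyDuplicated(df[c("cruise", "site")]))
    stop("duplicate (cruise, site) rows in metadata")
  bm <- df$biomass_ugC_L
  if (any(!is.na(bm) & bm <= 0)) stop("biomass_ugC_L must be positive")
  df
}

#' Write per-site metadata to TSV
#' @param metadata a metadata `data.frame` (see [read_metadata()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Cross-check community tables against metadata
#'
#' Verifies that every (cruise, site) present in the count tables has a
#' metadata row, and that every taxon resolves to a tip of the phylogeny
#' when one is supplied.
#'
#' @param tables list of `community_table`s.
#' @param metadata metadata `data.frame`.
#' @param tree optional `phylo`; when given, taxa must all be tips.
#' @return `TRUE`, invisibly; otherwise an error.
#' @export
check_dataset <- function(tables, metadata, tree = NULL) {
  meta_keys <- paste(metadata$cruise, metadata$site, sep = "\r")
  for (tab in tables) {
    keys <- paste(cruise_id(tab), rownames(tab), sep = "\r")
    miss <- setdiff(keys, meta_keys)
    if (length(miss) > 0)
      stop("sites present in counts but absent from metadata: ",
           paste(gsub("\r", "/", miss), collapse = ", "))
    if (!is.null(tree)) {
      lost <- setdiff(colnames(tab), tree$tip.label)
      if (length(lost) > 0)
        stop("taxa absent from the phylogeny: ",
             paste(utils::head(lost, 5), collapse = ", "))
    }
  }
  invisible(TRUE)
}
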