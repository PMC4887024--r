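#' Read a spectral-count matrix and its group map
#'
#' The count file is TSV with a header row of sample ids and the protein
#' id in the first column; the group file is TSV with columns `sample` and
#' `group` (values "high"/"low"). Proteins with zero counts in every
#' sample are dropped (count reported via `message()`).
#'
#' @param path count matrix TSV.
#' @param group_path group map TSV.
#' @return A validated [count_matrix()].
#' @export
read_count_matrix <- function(path, group_path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("count file needs a protein column and >= 1 sample", call. = FALSE)
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric counts in ", path, call. = FALSE)
  rownames(m) <- ids
  g <- read.delim(group_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(g)))
    stop("group file needs columns 'sample' and 'group'", call. = FALSE)
  count_matrix(m, stats::setNames(g$group, g$sample))
}

#' Write a count matrix (and optionally its group map) as TSV
#'
#' @param m a [count_matrix()].
#' @param path count TSV path.
#' @param group_path optional group-map TSV path.
#' @return Invisibly, `m`.
#' @export
write_count_matrix <- function(m, path, group_path = NULL) {
  write_tsv_matrix(m$counts, path, id_col = "protein")
  if (!is.null(group_path)) {
    write_tsv(data.frame(sample = names(m$groups), group = unname(m$groups),
                         stringsAsFactors = FALSE), group_path)
  }
  invisible(m)
}

#' Read a plain-text symbol list
#'
#' One symbol per line; symbols are upper-cased and whitespace-trimmed,
#' blank lines skipped, duplicates removed with a warning.
#'
#' @param path list file.
#' @return character vector of unique symbols.
#' @export
read_symbol_list <- function(path) {
  raw <- trimws(toupper(readLines(path)))
  raw <- raw[nzchar(raw)]
  if (anyDuplicated(raw)) warning(sum(duplicated(raw)), " duplicate symbol(s) removed")
  unique(raw)
}

#' Read a GMT term-set file
#'
#' Standard GMT: one term per line, tab-separated `term`, `description`,
#' then member symbols. Members are upper-cased, trimmed and deduplicated;
#' a term with zero members is retained as an empty set with a warning.
#'
#' @param path GMT file.
#' @return named list of character vectors (term -> members).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2) stop("malformed GMT line: ", substr(ln, 1, 40), call. = FALSE)
    members <- unique(toupper(trimws(f[-(1:2)])))
    members <- members[nzchar(members)]
    if (length(members) == 0) warning("GMT term '", f[1], "' has no members")
    out[[f[1]]] <- members
  }
  out
}

#' Write term sets as GMT
#' @param terms named list of character vectors.
#' @param path output path.
#' @param descriptions optional per-term descriptions (default the term id).
#' @return Invisibly, `terms`.
#' @export
write_gmt <- function(terms, path, descriptions = names(terms)) {
  writeLines(vapply(seq_along(terms), function(i) {
    paste(c(names(terms)[i], descriptions[i], terms[[i]]), collapse = "\t")
  }, character(1)), path)
  invisible(terms)
}

#' Read a signed regulator-target network
#'
#' TSV with columns `regulator`, `target`, `direction`; directions must be
#' +1 (activates) or -1 (represses).
#'
#' @param path network TSV.
#' @return data.frame with the three columns, symbols upper-cased and
#'   trimmed.
#' @export
read_regulator_network <- function(path) {
  g <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("regulator", "target", "direction") %in% names(g)))
    stop("network file needs columns regulator, target, direction", call. = FALSE)
  bad <- which(!g$direction %in% c(-1, 1))
  if (length(bad))
    stop("direction outside {+1,-1} at line ", bad[1] + 1, call. = FALSE)
  g$regulator <- toupper(trimws(g$regulator))
  g$target <- toupper(trimws(g$target))
  g
}

#' Write a simulated dataset to disk
#'
#' Emits the full synthetic bundle: counts TSV, group map TSV, compartment
#' symbol list, ground-truth TSV, and (when a network is supplied) the
#' regulator network TSV.
#'
#' @param sim a `"pif_sim"` from [simulate_counts()].
#' @param dir output directory (created if missing).
#' @param network optional `"regulator_network"`.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_sim <- function(sim, dir, network = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             groups = file.path(dir, "groups.tsv"),
             compartment = file.path(dir, "compartment.txt"),
             truth = file.path(dir, "truth.tsv"))
  write_count_matrix(sim$counts, paths["counts"], paths["groups"])
  writeLines(sim$truth$protein[sim$truth$compartment], paths["compartment"])
  write_tsv(sim$truth, paths["truth"])
  if (!is.null(network)) {
    paths["network"] <- file.path(dir, "network.tsv")
    write_tsv(as.data.frame(network), paths["network"])
  }
  invisible(paths)
}

# fixed-format TSV writers: '.' decimal, no quoting, deterministic output
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

write_tsv_matrix <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}
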