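# File formats: headerless matrix CSV/TSV, web-of-life style incidence CSV,
# food-web edge lists, and tidy TSV results with '#' metadata headers.

sep_for <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an interaction matrix from a delimited file
#'
#' Expects a headerless square table of floats, one row per species (row i =
#' effects on species i). The delimiter is inferred from the extension
#' (`.csv` = comma, otherwise tab) unless given.
#'
#' @param path file path.
#' @param names_path optional two-column TSV sidecar (species name, guild).
#' @param sep field separator override.
#' @return An [interaction_matrix()].
#' @export
read_matrix <- function(path, names_path = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  rows <- utils::read.table(path, sep = sep_for(path, sep), header = FALSE,
                            colClasses = "numeric", strip.white = TRUE)
  lens <- unique(lengths(strsplit(readLines(path, warn = FALSE),
                                  sep_for(path, sep), fixed = TRUE)))
  if (length(lens) > 1) {
    stop("ragged rows in ", path, ": row lengths ", paste(lens, collapse = ", "))
  }
  A <- as.matrix(rows)
  dimnames(A) <- NULL
  if (nrow(A) != ncol(A)) {
    stop(sprintf("matrix in %s is %d x %d, not square", path, nrow(A), ncol(A)))
  }
  guilds <- NULL
  if (!is.null(names_path)) {
    side <- utils::read.table(names_path, sep = "\t", header = FALSE,
                              stringsAsFactors = FALSE)
    if (nrow(side) != nrow(A)) stop("sidecar has ", nrow(side), " rows for ", nrow(A), " species")
    rownames(A) <- colnames(A) <- side[[1]]
    if (ncol(side) >= 2) guilds <- side[[2]]
  }
  interaction_matrix(A, guilds = guilds)
}

#' Write an interaction matrix (headerless CSV/TSV)
#'
#' Values are written in full double precision (`%.17g`) so a write/read
#' round trip is bitwise exact.
#'
#' @param A interaction matrix.
#' @param path output file; delimiter inferred from the extension.
#' @param names_path optional sidecar path for species names and guilds.
#' @param sep field separator override.
#' @export
write_matrix <- function(A, path, names_path = NULL, sep = NULL) {
  A0 <- check_square(A)
  s <- sep_for(path, sep)
  lines <- apply(A0, 1, function(row) paste(sprintf("%.17g", row), collapse = s))
  writeLines(lines, path)
  if (!is.null(names_path)) {
    nms <- rownames(unclass(A)) %||% paste0("sp", seq_len(nrow(A0)))
    g <- attr(A, "guilds") %||% rep("", nrow(A0))
    writeLines(paste(nms, g, sep = "\t"), names_path)
  }
  invisible(path)
}

#' Read a web-of-life style incidence matrix
#'
#' First row and first column carry species names; cells carry interaction
#' weights, binarized at weight > 0 (missing cells count as 0). Rows are
#' taken as the first guild (animals by default). Margin rows or columns
#' whose name matches "total"/"sum" are dropped with a message rather than
#' treated as species.
#'
#' @param path CSV file path.
#' @param rows_are `"animals"` or `"plants"`; if `"plants"`, the incidence is
#'   transposed so the returned network always has animals as rows.
#' @return A bipartite `adjacency_network`.
#' @export
read_incidence_csv <- function(path, rows_are = c("animals", "plants")) {
  rows_are <- match.arg(rows_are)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (nrow(df) == 0 || ncol(df) == 0) stop("empty incidence table in ", path)
  margin <- function(x) grepl("^(total|sum)", trimws(x), ignore.case = TRUE)
  drop_r <- margin(rownames(df)); drop_c <- margin(colnames(df))
  if (any(drop_r) || any(drop_c)) {
    message("dropping margin rows/columns: ",
            paste(c(rownames(df)[drop_r], colnames(df)[drop_c]), collapse = ", "))
    df <- df[!drop_r, !drop_c, drop = FALSE]
  }
  m <- as.matrix(df)
  suppressWarnings(storage.mode(m) <- "double")
  if (any(is.na(m) & !is.na(as.matrix(df)))) {
    bad <- which(is.na(m) & !is.na(as.matrix(df)), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at data row %d, column %d of %s",
                 bad[1], bad[2], path))
  }
  m[is.na(m)] <- 0
  if (all(m == 0)) stop("incidence matrix in ", path, " has no links")
  if (rows_are == "plants") m <- t(m)
  new_adjacency("bipartite", (m > 0) * 1,
                names_rows = rownames(m), names_cols = colnames(m))
}

#' Read a food-web edge list
#'
#' Tab-separated columns `resource_id` and `consumer_id` (a header row with
#' those names is detected and skipped). Duplicate edges are collapsed with
#' a warning; 2-cycles (both (a,b) and (b,a) present) raise an error since
#' downstream parameterization assumes loop-free predator-prey pairs.
#'
#' @param path TSV file path.
#' @return A directed `adjacency_network` with `L[i, j] = 1` meaning species
#'   j consumes species i, species ordered by sorted id.
#' @export
read_edgelist <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- strsplit(readLines(path, n = 1, warn = FALSE), "\t")[[1]]
  header <- any(grepl("resource|consumer", first, ignore.case = TRUE))
  df <- utils::read.table(path, sep = "\t", header = header,
                          stringsAsFactors = FALSE,
                          col.names = c("resource", "consumer"))
  if (nrow(df) == 0) stop("empty edge list in ", path)
  df$resource <- as.character(df$resource)
  df$consumer <- as.character(df$consumer)
  key <- paste(df$resource, df$consumer, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate edge(s) collapsed in ", path)
    df <- df[!duplicated(key), ]
  }
  rev_key <- paste(df$consumer, df$resource, sep = "\r")
  two_cycle <- df$resource != df$consumer &
    paste(df$resource, df$consumer, sep = "\r") %in% rev_key
  if (any(two_cycle)) {
    stop("2-cycle(s) in ", path, ": ",
         paste(utils::head(paste(df$resource[two_cycle], df$consumer[two_cycle],
                                 sep = " <-> "), 3), collapse = ", "),
         "; resolve or strip before use")
  }
  ids <- sort(unique(c(df$resource, df$consumer)))
  L <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  L[cbind(match(df$resource, ids), match(df$consumer, ids))] <- 1
  net <- new_adjacency("directed", unname(L), names_rows = ids)
  if (any(diag(unname(L)) != 0)) {
    warning("cannibalistic loop(s) present; see strip_cannibalism()")
    net <- new_adjacency("directed", unname(L), names_rows = ids)
  }
  net
}

#' Write a tidy results table
#'
#' Writes a TSV with `#`-prefixed metadata header lines (tool version, seed,
#' timestamp-free so outputs are reproducible) followed by the column header
#' and one row per computation. Refuses to overwrite unless `overwrite`.
#'
#' @param records data frame of results.
#' @param path output path.
#' @param meta named character vector of metadata to record.
#' @param overwrite allow replacing an existing file.
#' @export
write_results <- function(records, path, meta = character(), overwrite = FALSE) {
  stopifnot(is.data.frame(records))
  if (file.exists(path) && !overwrite) {
    stop("output file exists: ", path, " (use overwrite = TRUE)")
  }
  meta <- c(package = paste0("feasdom ", as.character(utils::packageVersion("feasdom"))), meta)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(meta), meta), con)
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
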