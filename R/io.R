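#' Read and write signed edge lists
#'
#' Edge lists are plain text with three columns `drug_a, drug_b, sign`
#' (comma- or tab-delimited; the delimiter is sniffed from the first line).
#' An optional header is detected by a non-numeric third field. Signs may be
#' written `1`, `+1` or `-1`. Validation mirrors [signed_network()]:
#' self-loops, non-sign values and conflicting duplicates are rejected with
#' the offending line numbers; consistent duplicates collapse.
#'
#' @param path File path.
#' @return A [signed_network()].
#' @export
read_signed_edgelist <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop_invalid(sprintf("Empty edge list: %s", path))
  delim <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
  fields <- strsplit(lines, delim, fixed = TRUE)
  bad_len <- which(lengths(fields) != 3)
  if (length(bad_len) > 0) {
    stop_invalid(sprintf("Line %d of %s does not have 3 fields.",
                         bad_len[1], path))
  }
  tab <- do.call(rbind, fields)
  tab <- apply(tab, 2, trimws)
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = 1)
  start <- 1L
  if (is.na(suppressWarnings(as.numeric(tab[1, 3])))) start <- 2L # header
  if (start > nrow(tab)) stop_invalid(sprintf("No edges in %s.", path))
  body <- tab[start:nrow(tab), , drop = FALSE]
  s <- suppressWarnings(as.numeric(body[, 3]))
  bad <- which(is.na(s) | !(s %in% c(-1, 1)))
  if (length(bad) > 0) {
    stop_invalid(sprintf(
      "Line %d of %s: sign `%s` is not +1 or -1.",
      bad[1] + start - 1L, path, body[bad[1], 3]
    ))
  }
  signed_network(tibble(drug_a = body[, 1], drug_b = body[, 2], sign = s))
}

#' @rdname read_signed_edgelist
#' @param net A [signed_network()].
#' @param delim Field delimiter (default comma).
#' @export
write_signed_edgelist <- function(net, path, delim = ",") {
  e <- network_edges(as_signed_network(net))
  sgn <- ifelse(e$sign > 0, "+1", "-1")
  lines <- c(paste(c("drug_a", "drug_b", "sign"), collapse = delim),
             paste(e$drug_a, e$drug_b, sgn, sep = delim))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Read and write binary feature tables
#'
#' Feature tables are delimited text with a mandatory header row: the first
#' column holds drug labels, the remaining columns binary protein (or
#' fingerprint) indicators named in the header. The writer emits a
#' byte-stable dialect: comma delimiter, feature columns sorted by name, LF
#' line endings.
#'
#' @param path File path.
#' @return A feature tibble (first column `drug`, then 0/1 columns).
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("File not found: %s", path))
  first <- readLines(path, n = 1, warn = FALSE)
  delim <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, progress = FALSE,
                          show_col_types = FALSE)
  if (nrow(df) == 0) stop_invalid(sprintf("Feature table %s has no rows.", path))
  if (ncol(df) < 2) stop_invalid(sprintf("Feature table %s has no feature columns.", path))
  names(df)[1] <- "drug"
  df$drug <- as.character(df$drug)
  numeric_cols <- vapply(df[-1], is.numeric, logical(1))
  if (!all(numeric_cols)) {
    stop_invalid(sprintf("Non-numeric feature column in %s: %s.",
                         path, names(df[-1])[!numeric_cols][1]))
  }
  feature_matrix(df) # validates binary entries and duplicate labels
  as_tibble(df)
}

#' @rdname read_feature_table
#' @param features A feature tibble or matrix (see [feature_matrix()]).
#' @export
write_feature_table <- function(features, path) {
  F_ <- feature_matrix(features)
  F_ <- F_[, order(colnames(F_)), drop = FALSE]
  header <- paste(c("drug", colnames(F_)), collapse = ",")
  rows <- paste(rownames(F_),
                apply(F_, 1, paste, collapse = ","), sep = ",")
  writeLines(c(header, rows), path, sep = "\n")
  invisible(path)
}

#' Read and write community partitions
#'
#' Two-column delimited text `drug, community_index` with a header row.
#'
#' @param path File path.
#' @return A tibble with columns `drug` and `community`.
#' @export
read_partition <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("File not found: %s", path))
  df <- readr::read_csv(path, col_types = "ci", progress = FALSE,
                        show_col_types = FALSE)
  if (ncol(df) < 2) stop_invalid("Partition file needs two columns.")
  names(df)[1:2] <- c("drug", "community")
  as_tibble(df[, 1:2])
}

#' @rdname read_partition
#' @param partition A partition tibble (`drug`, `community`).
#' @export
write_partition <- function(partition, path) {
  readr::write_csv(partition[, c("drug", "community")], path, eol = "\n")
  invisible(path)
}

#' Serialize a balance report to JSON
#'
#' @param report A [balance_report()].
#' @param path File path.
#' @export
write_balance_report <- function(report, path) {
  stopifnot(inherits(report, "balance_report"))
  jsonlite::write_json(
    list(cbi = report$cbi,
         communities = report$communities,
         pairs = report$pairs),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows", na = "null"
  )
  invisible(path)
}

#' Save and load a cold-start model as a directory of text files
#'
#' The model directory holds `W.csv`, `B.csv`, `H.csv` (labeled delimited
#' matrices) and `config.json` (labels, feature names, dimensions).
#'
#' @param model A `coldstart_model`.
#' @param dir Directory path (created if missing).
#' @export
write_coldstart_model <- function(model, dir) {
  stopifnot(inherits(model, "coldstart_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_labeled_matrix(model$W, file.path(dir, "W.csv"))
  write_labeled_matrix(model$B, file.path(dir, "B.csv"))
  write_labeled_matrix(model$H, file.path(dir, "H.csv"))
  jsonlite::write_json(
    list(labels = model$labels, feature_names = model$feature_names,
         k = model$k, ncomp = model$ncomp),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_coldstart_model
#' @export
read_coldstart_model <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  W <- read_labeled_matrix(file.path(dir, "W.csv"))
  B <- read_labeled_matrix(file.path(dir, "B.csv"))
  H <- read_labeled_matrix(file.path(dir, "H.csv"))
  structure(list(W = W, B = B, H = H, fit = NULL,
                 labels = cfg$labels, feature_names = cfg$feature_names,
                 k = cfg$k, ncomp = cfg$ncomp),
            class = "coldstart_model")
}

write_labeled_matrix <- function(M, path) {
  df <- as.data.frame(M)
  if (is.null(colnames(M))) names(df) <- paste0("c", seq_len(ncol(M)))
  rowlab <- rownames(M)
  if (is.null(rowlab)) rowlab <- paste0("r", seq_len(nrow(M)))
  out <- dplyr::bind_cols(tibble(label = rowlab), as_tibble(df))
  readr::write_csv(out, path, eol = "\n")
  invisible(path)
}

read_labeled_matrix <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    label = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE, show_col_types = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df$label
  M
}
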