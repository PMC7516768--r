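#' Read a size/degree sample from TSV
#'
#' Accepts either a one-column file of sizes or a two-column `size`/`count`
#' table (header optional in both cases).
#'
#' @param path Path to a TSV file.
#' @return Tibble with columns `size` and `count`.
#' @export
read_sizes_tsv <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("[A-Za-z]", first)
  df <- utils::read.table(path, header = has_header, sep = "\t")
  if (ncol(df) == 1) {
    df <- as.data.frame(table(df[[1]]), stringsAsFactors = FALSE)
    df[[1]] <- as.numeric(df[[1]])
  }
  names(df) <- c("size", "count")[seq_len(2)]
  as_tibble(df[order(df$size), ])
}

#' Expand a size/count table into a sample vector
#'
#' @param tbl Tibble with `size` and `count` columns (as from
#'   [read_sizes_tsv()]).
#' @return Numeric vector with each size repeated `count` times.
#' @export
as_size_vector <- function(tbl) {
  rep(tbl$size, times = tbl$count)
}

#' Write a size/degree sample as a two-column TSV
#'
#' Sizes are tabulated to `size`/`count` rows with a header line.
#'
#' @param sizes Vector of sizes.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sizes_tsv <- function(sizes, path) {
  tab <- as.data.frame(table(size = sizes), stringsAsFactors = FALSE)
  names(tab) <- c("size", "count")
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a run trajectory as TSV
#'
#' @param run An `urn_run`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(run, path) {
  utils::write.table(run$trajectory, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a process configuration from YAML or JSON
#'
#' Keys mirror the [urn_config()] / [network_config()] arguments (`T` is
#' accepted as an alias for `iterations`).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param type `"urn"` or `"network"`.
#' @return An `urn_config` or `network_config`.
#' @export
read_config_file <- function(path, type = c("urn", "network")) {
  type <- match.arg(type)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(vals$T) && is.null(vals$iterations)) {
    vals$iterations <- vals$T
  }
  vals$T <- NULL
  ctor <- if (type == "urn") urn_config else network_config
  ok <- intersect(names(vals), names(formals(ctor)))
  do.call(ctor, vals[ok])
}

#' Write a maximum-entropy solution or fit as flat JSON
#'
#' @param x A `maxent_solution`, `plcut_fit`, or `omega_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  flat <- x[vapply(x, function(v) is.numeric(v) && length(v) == 1 ||
                     is.logical(v) && length(v) == 1, logical(1))]
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
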