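#' @keywords internal
"_PACKAGE"

# ---- internal validation helpers ----

stop_schema <- function(msg) stop(errorCondition(msg, class = c("nitromix_schema_error", "nitromix_error")))
stop_parse  <- function(msg) stop(errorCondition(msg, class = c("nitromix_parse_error", "nitromix_error")))
stop_domain <- function(msg) stop(errorCondition(msg, class = c("nitromix_domain_error", "nitromix_error")))

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_schema(sprintf("%s: missing required column(s): %s",
                        what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

as_numeric_strict <- function(x, column, what) {
  if (is.numeric(x)) return(as.numeric(x))
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0L) {
    stop_parse(sprintf("%s: non-numeric value '%s' in column '%s' at data row %d",
                       what, x[bad[1L]], column, bad[1L]))
  }
  if (anyNA(out)) {
    stop_domain(sprintf("%s: missing value in column '%s' at data row %d (missing values are not permitted)",
                        what, column, which(is.na(out))[1L]))
  }
  out
}

# ---- isotope sample tables ----

#' Read a table of dual-isotope water samples
#'
#' Reads a CSV of per-sample nitrate isotope observations. Each row is one
#' water sample with its site/region/season labels and the measured
#' \eqn{\delta^{15}}N and \eqn{\delta^{18}}O values of nitrate in per-mil.
#'
#' @param path Path to a CSV file with columns
#'   \code{sample_id, region, season, d15n, d18o}.
#' @return A data frame of class \code{isotope_samples} with one row per
#'   sample and numeric \code{d15n}/\code{d18o} columns (per-mil).
#' @export
read_isotope_csv <- function(path) {
  if (!file.exists(path)) stop_schema(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_isotope_samples(df)
}

#' Validate a data frame of isotope samples
#'
#' @param df Data frame with columns \code{sample_id, region, season, d15n, d18o}.
#' @return The validated data frame with class \code{isotope_samples}.
#' @export
as_isotope_samples <- function(df) {
  require_columns(df, c("sample_id", "region", "season", "d15n", "d18o"),
                  "isotope table")
  df$d15n <- as_numeric_strict(df$d15n, "d15n", "isotope table")
  df$d18o <- as_numeric_strict(df$d18o, "d18o", "isotope table")
  if (any(!is.finite(df$d15n)) || any(!is.finite(df$d18o))) {
    stop_domain("isotope table: non-finite isotope value")
  }
  df$sample_id <- as.character(df$sample_id)
  df$region <- as.character(df$region)
  df$season <- as.character(df$season)
  if (any(!nzchar(df$region)) || any(!nzchar(df$season))) {
    stop_domain("isotope table: empty region or season label")
  }
  structure(df, class = c("isotope_samples", "data.frame"))
}

#' Write isotope samples to CSV
#'
#' @param samples An \code{isotope_samples} data frame.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_isotope_csv <- function(samples, path) {
  write_csv6(samples, path)
}

# numeric columns written at 6 significant digits, full precision kept in memory
write_csv6 <- function(df, path) {
  out <- as.data.frame(df)
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- signif(out[[j]], 12L)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- source signature tables ----

#' Construct a source signature table
#'
#' Holds, for every source \eqn{k} and isotope \eqn{j}, the source signature
#' distribution (mean \eqn{\mu_{jk}}, SD \eqn{\omega_{jk}}), the fractionation
#' distribution (mean \eqn{\lambda_{jk}}, SD \eqn{\tau_{jk}}) and a
#' concentration weight \eqn{q_{jk} > 0}. Observations are modelled as convex
#' combinations of (signature + fractionation), concentration-weighted,
#' plus residual error.
#'
#' @param df Long-format data frame with columns
#'   \code{source, isotope, mean_s, sd_s, mean_c, sd_c} and optionally
#'   \code{conc_q} (defaults to 1).
#' @return An object of class \code{source_signatures}: a list with
#'   \code{sources}, \code{isotopes} (character vectors) and J-by-K numeric
#'   matrices \code{mean_s, sd_s, mean_c, sd_c, conc_q} (rows = isotopes,
#'   columns = sources).
#' @export
source_signatures <- function(df) {
  require_columns(df, c("source", "isotope", "mean_s", "sd_s", "mean_c", "sd_c"),
                  "sources table")
  if (!"conc_q" %in% names(df)) df$conc_q <- 1
  for (cc in c("mean_s", "sd_s", "mean_c", "sd_c", "conc_q")) {
    df[[cc]] <- as_numeric_strict(df[[cc]], cc, "sources table")
  }
  if (any(df$sd_s < 0) || any(df$sd_c < 0)) {
    stop_domain("sources table: negative standard deviation")
  }
  if (any(df$conc_q <= 0)) stop_domain("sources table: conc_q must be > 0")
  sources  <- unique(as.character(df$source))
  isotopes <- unique(as.character(df$isotope))
  K <- length(sources); J <- length(isotopes)
  want <- expand.grid(isotope = isotopes, source = sources, stringsAsFactors = FALSE)
  have <- paste(df$source, df$isotope)
  gaps <- want[!paste(want$source, want$isotope) %in% have, , drop = FALSE]
  if (nrow(gaps) > 0L) {
    stop_schema(sprintf("sources table: missing source x isotope combination(s): %s",
                        paste(paste(gaps$source, gaps$isotope, sep = "/"), collapse = ", ")))
  }
  if (anyDuplicated(have)) stop_schema("sources table: duplicated source x isotope rows")
  mk <- function(col) {
    m <- matrix(NA_real_, J, K, dimnames = list(isotopes, sources))
    m[cbind(match(df$isotope, isotopes), match(df$source, sources))] <- df[[col]]
    m
  }
  structure(list(sources = sources, isotopes = isotopes,
                 mean_s = mk("mean_s"), sd_s = mk("sd_s"),
                 mean_c = mk("mean_c"), sd_c = mk("sd_c"),
                 conc_q = mk("conc_q")),
            class = "source_signatures")
}

#' Read a source signature table from CSV
#'
#' @param path CSV with long-format columns
#'   \code{source, isotope, mean_s, sd_s, mean_c, sd_c[, conc_q]}; every
#'   source-by-isotope pair must be present. When \code{conc_q} is absent all
#'   weights default to 1 (no concentration dependence).
#' @return A \code{source_signatures} object.
#' @export
read_sources_csv <- function(path) {
  if (!file.exists(path)) stop_schema(sprintf("file not found: %s", path))
  source_signatures(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a source signature table to CSV
#' @param sig A \code{source_signatures} object.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_sources_csv <- function(sig, path) {
  df <- signatures_to_long(sig)
  write_csv6(df, path)
}

signatures_to_long <- function(sig) {
  grid <- expand.grid(isotope = sig$isotopes, source = sig$sources,
                      stringsAsFactors = FALSE)
  idx <- cbind(match(grid$isotope, sig$isotopes), match(grid$source, sig$sources))
  data.frame(source = grid$source, isotope = grid$isotope,
             mean_s = sig$mean_s[idx], sd_s = sig$sd_s[idx],
             mean_c = sig$mean_c[idx], sd_c = sig$sd_c[idx],
             conc_q = sig$conc_q[idx], stringsAsFactors = FALSE)
}

#' @export
print.source_signatures <- function(x, ...) {
  cat(sprintf("Source signature table: %d sources (%s) x %d isotopes (%s)\n",
              length(x$sources), paste(x$sources, collapse = ", "),
              length(x$isotopes), paste(x$isotopes, collapse = ", ")))
  invisible(x)
}

# ---- community count tables ----

#' Read a sites-by-taxa count table
#'
#' Community tables are TSV (taxon names routinely contain commas). The first
#' column holds labels; remaining cells are non-negative integer counts.
#'
#' @param path TSV file path.
#' @param orientation Either \code{"sites-rows"} (default) or
#'   \code{"taxa-rows"}; the returned matrix is always sites x taxa.
#' @return A \code{community_table}: list with \code{counts} (integer matrix,
#'   sites x taxa, dimnames set), and optional \code{metadata}.
#' @export
read_community_table <- function(path, orientation = c("sites-rows", "taxa-rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop_schema(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop_parse("community table: need a label column plus at least one count column")
  labels <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m)))
  if (anyNA(num)) stop_parse("community table: non-numeric cell")
  if (any(num < 0)) stop_domain("community table: negative count")
  if (any(num != round(num))) stop_parse("community table: non-integer count (integers required)")
  counts <- matrix(as.integer(round(num)), nrow(m), ncol(m),
                   dimnames = list(labels, colnames(df)[-1L]))
  if (orientation == "taxa-rows") counts <- t(counts)
  community_table(counts)
}

#' Construct a community table from a counts matrix
#'
#' @param counts Non-negative integer matrix, sites as rows, taxa as columns.
#' @param metadata Optional per-site data frame (season/region labels).
#' @return A \code{community_table} object.
#' @export
community_table <- function(counts, metadata = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (any(counts < 0)) stop_domain("community table: negative count")
  if (is.null(rownames(counts))) rownames(counts) <- paste0("site", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("taxon", seq_len(ncol(counts)))
  structure(list(counts = counts, metadata = metadata), class = "community_table")
}

#' Write a community table to TSV (sites as rows)
#' @param tab A \code{community_table}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_community_table <- function(tab, path) {
  df <- data.frame(site_id = rownames(tab$counts), tab$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("Community table: %d sites x %d taxa, total count %s\n",
              nrow(x$counts), ncol(x$counts), format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

# ---- watershed covariate tables ----

watershed_required_cols <- c("site_id", "season", "connectivity", "tn", "no3",
                             "nh4", "chao1", "shannon", "agriculture",
                             "population", "wastewater", "environment")

#' Read a watershed covariate table
#'
#' One record per site/season: the river-lake connectivity index, nitrogen
#' concentrations (mg/l), alpha-diversity summaries and the socio-environmental
#' covariates used by the coupling and path analyses.
#'
#' @param path CSV with columns
#'   \code{site_id, season, connectivity, tn, no3, nh4, chao1, shannon,
#'   agriculture, population, wastewater, environment}.
#' @return A data frame of class \code{watershed_table}.
#' @export
read_watershed_csv <- function(path) {
  if (!file.exists(path)) stop_schema(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_watershed_table(df)
}

#' Validate a watershed covariate table
#' @param df Data frame with the watershed CSV columns.
#' @return The validated data frame, classed \code{watershed_table}.
#' @export
as_watershed_table <- function(df) {
  require_columns(df, watershed_required_cols, "watershed table")
  for (cc in setdiff(watershed_required_cols, c("site_id", "season"))) {
    df[[cc]] <- as_numeric_strict(df[[cc]], cc, "watershed table")
  }
  if (any(!is.finite(df$connectivity))) stop_domain("watershed table: non-finite connectivity")
  for (cc in c("tn", "no3", "nh4")) {
    if (any(df[[cc]] < 0)) stop_domain(sprintf("watershed table: negative %s concentration", cc))
  }
  structure(df, class = c("watershed_table", "data.frame"))
}

#' Write a watershed table to CSV
#' @param df A \code{watershed_table}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_watershed_csv <- function(df, path) {
  write_csv6(df, path)
}

# ---- distance matrices ----

#' Construct a labelled distance matrix
#'
#' @param values Square symmetric numeric matrix, zero diagonal,
#'   non-negative off-diagonals.
#' @param labels Optional labels (defaults to existing dimnames or d1..dn).
#' @return A \code{dist_matrix} object (the validated matrix with labels).
#' @export
dist_matrix <- function(values, labels = NULL) {
  if (!is.matrix(values) || nrow(values) != ncol(values)) {
    stop_domain("distance matrix must be square")
  }
  if (is.null(labels)) labels <- rownames(values)
  if (is.null(labels)) labels <- paste0("d", seq_len(nrow(values)))
  if (max(abs(values - t(values))) > 1e-12) stop_domain("distance matrix must be symmetric (1e-12)")
  if (any(diag(values) != 0)) stop_domain("distance matrix must have a zero diagonal")
  if (any(values < 0)) stop_domain("distance matrix must be non-negative")
  dimnames(values) <- list(labels, labels)
  structure(values, class = c("dist_matrix", "matrix"))
}

# ---- result writing ----

#' Write a set of result tables plus a run manifest
#'
#' Emits one CSV per named table and a \code{manifest.json} recording the
#' seed, the configuration used, and package/R versions, so a run can be
#' reproduced exactly.
#'
#' @param tables Named list of data frames.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed associated with the run.
#' @param config Optional configuration list echoed into the manifest.
#' @return Character vector of file paths written, invisibly.
#' @export
write_results <- function(tables, dir, seed = NA_integer_, config = list()) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, mode = 2L) != 0L) {
    stop(errorCondition(sprintf("cannot write to directory: %s", dir),
                        class = c("nitromix_io_error", "nitromix_error")))
  }
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    write_csv6(as.data.frame(tables[[nm]]), p)
    paths <- c(paths, p)
  }
  manifest <- list(
    seed = seed,
    config = config,
    config_hash = rlang::hash(config),
    tables = names(tables),
    package = "nitromix",
    package_version = as.character(utils::packageVersion("nitromix")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(paths, mp))
}
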