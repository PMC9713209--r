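# Enumerations used throughout. Blood is separated into CD3/CD19/CD33 only;
# CD34 enrichment is performed on bone marrow aspirates.
LINEAGES        <- c("CD3", "CD19", "CD33", "CD34")
COMPARTMENTS    <- c("blood", "marrow")
BLOOD_LINEAGES  <- c("CD3", "CD19", "CD33")
MARROW_LINEAGES <- c("CD3", "CD19", "CD33", "CD34")

TRANSPLANT_COLS  <- c("transplant_id", "patient_id", "age_years", "relapse_day",
                      "censor_day", "conditioning", "atg", "source", "donor")
MEASUREMENT_COLS <- c("transplant_id", "day", "compartment", "lineage",
                      "percent_recipient")

#' Construct and validate a chimerism cohort
#'
#' A cohort bundles one row per transplantation (outcome and covariates) with
#' a long table of chimerism results (one row per assayed cell fraction per
#' sample). Chimerism is expressed as percent recipient DNA on the 0-100
#' scale; 0 means complete donor chimerism. Day 0 is the day of
#' transplantation. Multiple transplants may share a \code{patient_id} (re-
#' transplanted patients); each transplantation is treated as an independent
#' analysis unit.
#'
#' @param transplants data.frame with columns \code{transplant_id},
#'   \code{patient_id}, \code{age_years}, \code{relapse_day} (NA when no
#'   relapse was observed), \code{censor_day} (death or last follow-up),
#'   \code{conditioning} ("MAC"/"RIC"), \code{atg} (0/1), \code{source}
#'   ("BM"/"PB"), \code{donor} ("SIB"/"HAPLO"/"MUD").
#' @param measurements data.frame with columns \code{transplant_id},
#'   \code{day}, \code{compartment} ("blood"/"marrow"), \code{lineage}
#'   ("CD3"/"CD19"/"CD33"/"CD34"), \code{percent_recipient}, and optionally
#'   \code{below_detection} (0/1; results reported as negative/below the
#'   detection limit are stored as 0.0 with this flag set).
#' @return An object of class \code{chim_cohort}: a list with validated,
#'   type-coerced \code{transplants} and \code{measurements} data frames.
#' @export
cohort <- function(transplants, measurements) {
  transplants  <- coerce_transplants(transplants)
  measurements <- coerce_measurements(measurements)
  validate_cohort_tables(transplants, measurements)
  structure(list(transplants = transplants, measurements = measurements),
            class = "chim_cohort")
}

#' @export
print.chim_cohort <- function(x, ...) {
  n_rel <- sum(!is.na(x$transplants$relapse_day))
  cat(sprintf("<chim_cohort> %d transplants (%d relapsed), %d measurements\n",
              nrow(x$transplants), n_rel, nrow(x$measurements)))
  invisible(x)
}

# Coerce a column, collecting the 1-based row numbers that fail.
coerce_col <- function(df, col, fn, what, allow_na = FALSE) {
  raw <- df[[col]]
  val <- suppressWarnings(fn(raw))
  bad <- is.na(val) & !(allow_na & (is.na(raw) | trimws(as.character(raw)) == ""))
  if (any(bad)) {
    stop(sprintf("column '%s': cannot parse as %s in row(s) %s",
                 col, what, paste(utils::head(which(bad), 5), collapse = ", ")),
         call. = FALSE)
  }
  val
}

require_cols <- function(df, cols, table) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0)
    stop(sprintf("%s table: missing required column(s): %s",
                 table, paste(miss, collapse = ", ")), call. = FALSE)
}

check_enum <- function(x, levels, col, table) {
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad))
    stop(sprintf("%s table: column '%s' has invalid value(s) %s in row(s) %s (allowed: %s)",
                 table, col, paste(unique(x[bad]), collapse = ", "),
                 paste(utils::head(which(bad), 5), collapse = ", "),
                 paste(levels, collapse = "|")), call. = FALSE)
}

coerce_transplants <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  require_cols(df, TRANSPLANT_COLS, "transplants")
  out <- data.frame(
    transplant_id = as.character(df$transplant_id),
    patient_id    = as.character(df$patient_id),
    age_years     = coerce_col(df, "age_years", as.numeric, "numeric"),
    relapse_day   = coerce_col(df, "relapse_day", function(x) as.integer(round(as.numeric(x))),
                               "integer", allow_na = TRUE),
    censor_day    = coerce_col(df, "censor_day", function(x) as.integer(round(as.numeric(x))),
                               "integer"),
    conditioning  = as.character(df$conditioning),
    atg           = coerce_col(df, "atg", function(x) as.integer(as.numeric(x)), "0/1 flag"),
    source        = as.character(df$source),
    donor         = as.character(df$donor),
    stringsAsFactors = FALSE
  )
  check_enum(out$conditioning, c("MAC", "RIC"), "conditioning", "transplants")
  check_enum(out$source, c("BM", "PB"), "source", "transplants")
  check_enum(out$donor, c("SIB", "HAPLO", "MUD"), "donor", "transplants")
  check_enum(out$atg, c(0L, 1L), "atg", "transplants")
  rownames(out) <- NULL
  out
}

coerce_measurements <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  require_cols(df, MEASUREMENT_COLS, "measurements")
  bd <- if ("below_detection" %in% names(df)) {
    coerce_col(df, "below_detection", function(x) as.integer(as.numeric(x)), "0/1 flag")
  } else {
    rep(0L, nrow(df))
  }
  out <- data.frame(
    transplant_id     = as.character(df$transplant_id),
    day               = coerce_col(df, "day", function(x) as.integer(round(as.numeric(x))), "integer"),
    compartment       = as.character(df$compartment),
    lineage           = as.character(df$lineage),
    percent_recipient = coerce_col(df, "percent_recipient", as.numeric, "numeric"),
    below_detection   = bd,
    stringsAsFactors  = FALSE
  )
  check_enum(out$compartment, COMPARTMENTS, "compartment", "measurements")
  check_enum(out$lineage, LINEAGES, "lineage", "measurements")
  rownames(out) <- NULL
  out
}

validate_cohort_tables <- function(transplants, measurements) {
  if (anyDuplicated(transplants$transplant_id))
    stop("transplants table: duplicated transplant_id: ",
         paste(unique(transplants$transplant_id[duplicated(transplants$transplant_id)]),
               collapse = ", "), call. = FALSE)
  bad <- which(measurements$percent_recipient < 0 | measurements$percent_recipient > 100)
  if (length(bad) > 0)
    stop(sprintf("measurements table: percent_recipient outside [0, 100] in row(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  bad <- which(measurements$day < 0)
  if (length(bad) > 0)
    stop(sprintf("measurements table: negative day in row(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  bad <- which(measurements$lineage == "CD34" & measurements$compartment != "marrow")
  if (length(bad) > 0)
    stop(sprintf("measurements table: CD34 outside marrow in row(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  orphan <- which(!(measurements$transplant_id %in% transplants$transplant_id))
  if (length(orphan) > 0)
    stop(sprintf("measurements table: unknown transplant_id %s in row(s) %s",
                 paste(utils::head(unique(measurements$transplant_id[orphan]), 3), collapse = ", "),
                 paste(utils::head(orphan, 5), collapse = ", ")), call. = FALSE)
  bad <- which(transplants$censor_day < 0)
  if (length(bad) > 0)
    stop(sprintf("transplants table: negative censor_day in row(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

#' Load a cohort from delimited text files
#'
#' @param transplants_path,measurements_path paths to header-bearing delimited
#'   text files (see \code{\link{cohort}} for the column contracts).
#' @param sep field delimiter; tab by default, \code{","} for CSV. Decimal
#'   point only (no comma decimals).
#' @return A validated \code{chim_cohort}.
#' @export
load_cohort <- function(transplants_path, measurements_path, sep = "\t") {
  for (p in c(transplants_path, measurements_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  tr <- utils::read.table(transplants_path, header = TRUE, sep = sep,
                          colClasses = "character", quote = "",
                          stringsAsFactors = FALSE, check.names = TRUE)
  me <- utils::read.table(measurements_path, header = TRUE, sep = sep,
                          colClasses = "character", quote = "",
                          stringsAsFactors = FALSE, check.names = TRUE)
  cohort(tr, me)
}

#' Write a cohort to delimited text files
#'
#' Output is readable by \code{\link{load_cohort}};
#' \code{load_cohort(write_cohort(x))} reproduces \code{x} field for field.
#'
#' @param x a \code{chim_cohort}
#' @param transplants_path,measurements_path output paths
#' @param sep field delimiter (tab by default)
#' @export
write_cohort <- function(x, transplants_path, measurements_path, sep = "\t") {
  stopifnot(inherits(x, "chim_cohort"))
  tr <- x$transplants
  tr$relapse_day <- ifelse(is.na(tr$relapse_day), "", as.character(tr$relapse_day))
  utils::write.table(tr, transplants_path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(x$measurements, measurements_path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(x)
}

#' Extract same-day paired blood/marrow samples
#'
#' Whenever blood and bone marrow were assayed on the same day for the same
#' transplant and lineage, the two results form a paired sample. A
#' (transplant, day) stratum with replicate results on either side is
#' ambiguous and excluded with a warning.
#'
#' @param x a \code{chim_cohort}
#' @param lineage one of "CD3", "CD19", "CD33"
#' @return data.frame with columns \code{transplant_id}, \code{day},
#'   \code{lineage}, \code{blood_percent}, \code{marrow_percent}.
#' @export
paired_samples <- function(x, lineage = "CD3") {
  stopifnot(inherits(x, "chim_cohort"), lineage %in% LINEAGES)
  m <- x$measurements[x$measurements$lineage == lineage, , drop = FALSE]
  key <- paste(m$transplant_id, m$day, sep = "\r")
  blood  <- m[m$compartment == "blood",  , drop = FALSE]
  marrow <- m[m$compartment == "marrow", , drop = FALSE]
  kb <- key[m$compartment == "blood"]
  km <- key[m$compartment == "marrow"]
  both <- intersect(kb, km)
  dup <- union(names(which(table(kb) > 1)), names(which(table(km) > 1)))
  amb <- intersect(both, dup)
  if (length(amb) > 0)
    warning(sprintf("%d (transplant, day) pair(s) excluded due to replicate same-day %s results",
                    length(amb), lineage), call. = FALSE)
  keep <- setdiff(both, amb)
  if (length(keep) == 0) {
    return(data.frame(transplant_id = character(0), day = integer(0),
                      lineage = character(0), blood_percent = numeric(0),
                      marrow_percent = numeric(0), stringsAsFactors = FALSE))
  }
  ib <- match(keep, kb)
  im <- match(keep, km)
  out <- data.frame(
    transplant_id  = blood$transplant_id[ib],
    day            = blood$day[ib],
    lineage        = lineage,
    blood_percent  = blood$percent_recipient[ib],
    marrow_percent = marrow$percent_recipient[im],
    stringsAsFactors = FALSE
  )
  out[order(out$transplant_id, out$day), , drop = FALSE]
}

#' Pearson correlation of paired blood/marrow chimerism
#'
#' @param pairs output of \code{\link{paired_samples}}
#' @return list with \code{r} (Pearson product-moment coefficient) and
#'   \code{n} (number of pairs).
#' @export
paired_correlation <- function(pairs) {
  n <- nrow(pairs)
  if (n < 3) stop("need at least 3 paired samples", call. = FALSE)
  x <- pairs$blood_percent
  y <- pairs$marrow_percent
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("degenerate variance: one coordinate is constant", call. = FALSE)
  list(r = stats::cor(x, y), n = n)
}
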