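#' Write a cohort to CSV files
#'
#' Writes `cycles.csv` and `embryos.csv` into `dir` (missing values as empty
#' fields) plus, when the cohort carries its generating configuration, a
#' `generator_config.json` sidecar with the numeric settings and deparsed
#' effect functions.
#'
#' @param cycles,embryos cohort tables (or a single list with both, as
#'   returned by [generate_cohort()], passed as `cycles`).
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cycles, embryos = NULL, dir) {
  cfg <- NULL
  if (is.null(embryos) && is.list(cycles) && !is.data.frame(cycles)) {
    cfg <- attr(cycles, "config")
    embryos <- cycles$embryos
    cycles <- cycles$cycles
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cycles, file.path(dir, "cycles.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(embryos, file.path(dir, "embryos.csv"),
                   row.names = FALSE, na = "")
  if (!is.null(cfg)) {
    side <- unclass(cfg)
    side$true_effects <- lapply(unclass(side$true_effects), function(v)
      if (is.function(v)) paste(deparse(v), collapse = " ") else v)
    jsonlite::write_json(side, file.path(dir, "generator_config.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(dir)
}

req_cycle_cols <- c("cycle_id", "maternal_age", "transfer_type",
                    "insemination")
req_embryo_cols <- c("embryo_id", "cycle_id", "tPNf", "t2", "t3", "t4",
                     "vp_duration", "fragmentation_pct", "multinucleated",
                     "live_birth")

#' Read and validate a cohort from CSV files
#'
#' Parses the two cohort tables, coerces types, treats empty cells as
#' missing, and enforces the record invariants: positive t2, t3 >= t2,
#' t4 >= t3 and tPNf <= t2 where present, binary outcome and
#' multinucleation flags, known transfer/insemination codes, embryos
#' referencing existing cycles, and exactly 1 embryo per SET / 2 per DET
#' cycle. Violations are reported with their (1-based, header-excluded) row
#' numbers.
#'
#' @param cycles_path,embryos_path CSV file paths.
#' @return list with validated `cycles` and `embryos` data frames.
#' @export
read_cohort <- function(cycles_path, embryos_path) {
  for (p in c(cycles_path, embryos_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  cycles <- utils::read.csv(cycles_path, stringsAsFactors = FALSE,
                            na.strings = "")
  embryos <- utils::read.csv(embryos_path, stringsAsFactors = FALSE,
                             na.strings = "")
  miss_c <- setdiff(req_cycle_cols, names(cycles))
  if (length(miss_c))
    stop("cycles.csv missing column(s): ", paste(miss_c, collapse = ", "),
         call. = FALSE)
  miss_e <- setdiff(req_embryo_cols, names(embryos))
  if (length(miss_e))
    stop("embryos.csv missing column(s): ", paste(miss_e, collapse = ", "),
         call. = FALSE)
  for (cn in c("tPNf", "t2", "t3", "t4", "vp_duration", "fragmentation_pct"))
    embryos[[cn]] <- as.numeric(embryos[[cn]])
  embryos$multinucleated <- as.integer(embryos$multinucleated)
  embryos$live_birth <- as.integer(embryos$live_birth)
  cycles$maternal_age <- as.numeric(cycles$maternal_age)

  bad <- function(cond) which(cond %in% TRUE)
  problems <- character(0)
  note <- function(rows, what, table) {
    if (length(rows))
      problems <<- c(problems, sprintf(
        "%s row(s) %s: %s", table,
        paste(utils::head(rows, 10L), collapse = ","), what))
  }
  note(bad(!cycles$transfer_type %in% c("SET", "DET")),
       "transfer_type must be SET or DET", "cycles")
  note(bad(!cycles$insemination %in% c("IVF", "ICSI")),
       "insemination must be IVF or ICSI", "cycles")
  note(bad(is.na(cycles$maternal_age)), "missing maternal_age", "cycles")
  note(bad(is.na(embryos$t2) | embryos$t2 <= 0), "t2 must be > 0", "embryos")
  note(bad(embryos$t3 < embryos$t2), "t3 < t2", "embryos")
  note(bad(embryos$t4 < embryos$t3), "t4 < t3", "embryos")
  note(bad(embryos$tPNf > embryos$t2), "tPNf > t2", "embryos")
  note(bad(!embryos$live_birth %in% c(0L, 1L)),
       "live_birth must be 0/1", "embryos")
  note(bad(!embryos$multinucleated %in% c(0L, 1L)),
       "multinucleated must be 0/1", "embryos")
  note(bad(!embryos$cycle_id %in% cycles$cycle_id),
       "unknown cycle_id", "embryos")
  cnt <- table(factor(embryos$cycle_id, levels = cycles$cycle_id))
  expected <- ifelse(cycles$transfer_type == "SET", 1L, 2L)
  mism <- which(as.integer(cnt) != expected)
  if (length(mism))
    problems <- c(problems, sprintf(
      "cycle(s) %s: embryo count does not match transfer type",
      paste(utils::head(cycles$cycle_id[mism], 10L), collapse = ",")))
  if (length(problems))
    stop("cohort validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  list(cycles = cycles, embryos = embryos)
}
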