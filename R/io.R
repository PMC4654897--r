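#' Linkage configuration for cohort assembly
#'
#' @param diagnosis_whitelist ICD-10 codes that define a case; dotted and
#'   undotted dialects ("M16.0", "M160") are equivalent after normalisation.
#' @param window_start,window_end Calendar dates delimiting the registry
#'   observation window.
#' @param zygosity_excluded Zygosity codes excluded from analysis (default
#'   `UZ`, unknown/uncertain zygosity).
#' @param dedupe_rule How repeat operations for one person are collapsed;
#'   only `"first_operation"` is implemented (a bilateral replacement with
#'   two recordings counts once, at the first operation).
#' @return An object of class `linkage_config`.
#' @export
linkage_config <- function(diagnosis_whitelist = c("M16.0", "M16.1"),
                           window_start = "1995-01-01",
                           window_end = "2010-08-31",
                           zygosity_excluded = "UZ",
                           dedupe_rule = "first_operation") {
  if (length(diagnosis_whitelist) == 0) stop("diagnosis_whitelist must be non-empty")
  window_start <- as.Date(window_start); window_end <- as.Date(window_end)
  if (!(window_start < window_end)) stop("window_start must precede window_end")
  dedupe_rule <- match.arg(dedupe_rule, "first_operation")
  structure(list(diagnosis_whitelist = normalize_icd10(diagnosis_whitelist),
                 window_start = window_start, window_end = window_end,
                 zygosity_excluded = zygosity_excluded, dedupe_rule = dedupe_rule),
            class = "linkage_config")
}

#' Normalise ICD-10 codes across dotted/undotted dialects
#'
#' `"M16.0"`, `"m160"` and `" M16.0 "` all normalise to `"M160"`.
#'
#' @param code Character vector of ICD-10 codes.
#' @return Normalised codes.
#' @export
normalize_icd10 <- function(code) {
  toupper(gsub("[. ]", "", trimws(code)))
}

read_delim_sniff <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delim)) {
    dt <- data.table::fread(path, colClasses = "character", na.strings = NULL)
  } else {
    dt <- data.table::fread(path, sep = delim, colClasses = "character", na.strings = NULL)
  }
  as.data.frame(dt, stringsAsFactors = FALSE)
}

parse_iso_dates <- function(x, what, required = TRUE) {
  x <- trimws(x)
  empty <- is.na(x) | x == ""
  out <- as.Date(rep(NA_integer_, length(x)))
  parsed <- as.Date(x[!empty], format = "%Y-%m-%d", optional = TRUE)
  bad <- is.na(parsed)
  if (any(bad)) {
    rows <- which(!empty)[bad]
    stop("unparseable ", what, " (expect ISO-8601 yyyy-mm-dd) at row(s): ",
         paste(utils::head(rows, 10), collapse = ", "))
  }
  if (required && any(empty))
    stop("missing ", what, " at row(s): ",
         paste(utils::head(which(empty), 10), collapse = ", "))
  out[!empty] <- parsed
  out
}

#' Read a twin-register file
#'
#' Expects a delimited text file with header columns `person_id`, `pair_id`,
#' `sex`, `zygosity`, `birth_date` and optionally `death_date`,
#' `emigration_date` (ISO-8601; empty when not applicable). Rows are
#' validated: duplicate person ids are an error; pairs with a number of
#' members other than two are excluded with a warning; pair members must
#' share `pair_id`, `birth_date` and `zygosity`; an MZ or same-sex-DZ pair
#' with discordant sexes, or an opposite-sex-DZ pair with concordant sexes,
#' is a hard error naming the pair.
#'
#' @param path File path (CSV/TSV; delimiter sniffed unless given).
#' @param delim Optional explicit field delimiter.
#' @return A `data.frame` of pre-event twin records.
#' @export
load_twin_register <- function(path, delim = NULL) {
  df <- read_delim_sniff(path, delim)
  need <- c("person_id", "pair_id", "sex", "zygosity", "birth_date")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("twin register is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$person_id))
    stop("duplicate person_id in twin register: ",
         paste(utils::head(unique(df$person_id[duplicated(df$person_id)]), 5), collapse = ", "))
  df$sex <- tolower(trimws(df$sex))
  if (!all(df$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  df$zygosity <- toupper(trimws(df$zygosity))
  df$birth_date <- parse_iso_dates(df$birth_date, "birth_date")
  df$death_date <- if ("death_date" %in% names(df))
    parse_iso_dates(df$death_date, "death_date", required = FALSE) else as.Date(rep(NA, nrow(df)))
  df$emigration_date <- if ("emigration_date" %in% names(df))
    parse_iso_dates(df$emigration_date, "emigration_date", required = FALSE) else as.Date(rep(NA, nrow(df)))

  size <- table(df$pair_id)
  odd <- names(size)[size != 2]
  if (length(odd)) {
    warning(sum(df$pair_id %in% odd), " individual(s) in pair(s) without exactly two members excluded: ",
            paste(utils::head(odd, 5), collapse = ", "))
  }
  dropped <- df[df$pair_id %in% odd, , drop = FALSE]
  df <- df[!df$pair_id %in% odd, , drop = FALSE]

  if (nrow(df)) {
    ord <- order(df$pair_id, df$person_id)
    df <- df[ord, ]
    i1 <- seq(1, nrow(df), by = 2); i2 <- i1 + 1
    same_sex <- df$sex[i1] == df$sex[i2]
    zyg <- df$zygosity[i1]
    if (any(df$zygosity[i2] != zyg))
      stop("pair members disagree on zygosity: ",
           paste(utils::head(df$pair_id[i1][df$zygosity[i2] != zyg], 5), collapse = ", "))
    if (any(df$birth_date[i1] != df$birth_date[i2]))
      stop("pair members disagree on birth_date: ",
           paste(utils::head(df$pair_id[i1][df$birth_date[i1] != df$birth_date[i2]], 5), collapse = ", "))
    bad_ss <- zyg %in% c("MZ", "DZSS") & !same_sex
    bad_os <- zyg == "DZOS" & same_sex
    if (any(bad_ss))
      stop("MZ/DZSS pair(s) with opposite sexes: ",
           paste(utils::head(df$pair_id[i1][bad_ss], 5), collapse = ", "))
    if (any(bad_os))
      stop("DZOS pair(s) with same sex: ",
           paste(utils::head(df$pair_id[i1][bad_os], 5), collapse = ", "))
    df$member_index <- 0L
    df$member_index[i1] <- 1L; df$member_index[i2] <- 2L
  } else {
    df$member_index <- integer(0)
  }
  rownames(df) <- NULL
  attr(df, "excluded_incomplete") <- nrow(dropped)
  df
}

#' Read an arthroplasty/event register file
#'
#' Expects columns `person_id`, `operation_date`, `diagnosis_code`; several
#' rows per person are allowed (bilateral operations are de-duplicated later
#' during cohort assembly, not here). An empty file yields an empty
#' collection.
#'
#' @inheritParams load_twin_register
#' @return A `data.frame` of operation records.
#' @export
load_event_register <- function(path, delim = NULL) {
  df <- read_delim_sniff(path, delim)
  if (nrow(df) == 0) {
    return(data.frame(person_id = character(), operation_date = as.Date(character()),
                      diagnosis_code = character(), stringsAsFactors = FALSE))
  }
  need <- c("person_id", "operation_date", "diagnosis_code")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("event register is missing column(s): ", paste(miss, collapse = ", "))
  df$operation_date <- parse_iso_dates(df$operation_date, "operation_date")
  df$diagnosis_code <- trimws(df$diagnosis_code)
  df[need]
}

#' Assemble the analysis cohort from linked registers
#'
#' Applies the exclusion flow: events are restricted to whitelist diagnoses
#' inside the observation window; per person the first qualifying operation
#' defines case status and exit age; twins with excluded (unknown) zygosity
#' are removed; pairs not both alive at the window start are removed; exit
#' cause is the earliest of operation, death and censoring
#' (administrative window end or emigration), with an exact tie going to the
#' operation (a recorded operation implies the person was alive). Ages are
#' exact day differences divided by 365.25.
#'
#' @param twins Output of [load_twin_register()].
#' @param events Output of [load_event_register()].
#' @param config A [linkage_config()].
#' @return A `twin_cohort` data.frame with the same columns as
#'   [simulate_cohort()]; the exclusion ledger (named counts of excluded
#'   individuals, mirroring a flow chart) is available via
#'   [exclusion_ledger()], and dropped events that reference unknown persons
#'   are counted in attribute `dropped_events`.
#' @export
build_analysis_cohort <- function(twins, events, config = linkage_config()) {
  stopifnot(inherits(config, "linkage_config"))
  input_n <- nrow(twins) + (attr(twins, "excluded_incomplete") %||% 0L)
  ledger <- c(incomplete_pair = attr(twins, "excluded_incomplete") %||% 0L)

  # exclusion: unknown/uncertain zygosity
  excl_zyg <- twins$zygosity %in% config$zygosity_excluded
  ledger["zygosity_excluded"] <- sum(excl_zyg)
  twins <- twins[!excl_zyg, , drop = FALSE]

  # exclusion: pairs not both alive at window start
  dead_pre <- (!is.na(twins$death_date) & twins$death_date < config$window_start) |
    (!is.na(twins$emigration_date) & twins$emigration_date < config$window_start)
  gone_pairs <- unique(twins$pair_id[dead_pre])
  excl_alive <- twins$pair_id %in% gone_pairs
  ledger["pair_not_alive_at_start"] <- sum(excl_alive)
  twins <- twins[!excl_alive, , drop = FALSE]

  # events: whitelist + window + known person + first qualifying operation
  ev <- events
  dropped_events <- 0L
  if (nrow(ev)) {
    ev$diagnosis_code_norm <- normalize_icd10(ev$diagnosis_code)
    ev <- ev[ev$diagnosis_code_norm %in% config$diagnosis_whitelist, , drop = FALSE]
    ev <- ev[ev$operation_date >= config$window_start &
               ev$operation_date <= config$window_end, , drop = FALSE]
    unknown <- !(ev$person_id %in% twins$person_id)
    if (any(unknown)) {
      dropped_events <- sum(unknown)
      message(dropped_events, " event(s) reference person_id absent from the twin register; dropped")
      ev <- ev[!unknown, , drop = FALSE]
    }
    if (nrow(ev)) {
      ev <- ev[order(ev$person_id, ev$operation_date), ]
      ev <- ev[!duplicated(ev$person_id), , drop = FALSE]   # first_operation rule
    }
  }

  birth <- twins$birth_date
  entry_age <- pmax(0, as.numeric(config$window_start - birth) / 365.25)
  admin_age <- as.numeric(config$window_end - birth) / 365.25
  cens_age <- pmin(admin_age,
                   ifelse(is.na(twins$emigration_date), Inf,
                          as.numeric(twins$emigration_date - birth) / 365.25))
  death_age <- ifelse(is.na(twins$death_date), Inf,
                      as.numeric(twins$death_date - birth) / 365.25)
  m <- match(twins$person_id, if (nrow(ev)) ev$person_id else character(0))
  case_age <- ifelse(is.na(m), Inf,
                     as.numeric((if (nrow(ev)) ev$operation_date else as.Date(character()))[m] - birth) / 365.25)
  code <- if (nrow(ev)) ev$diagnosis_code[m] else rep(NA_character_, nrow(twins))

  exit_age <- pmin(case_age, death_age, cens_age)
  cause <- ifelse(case_age <= exit_age, "case",
                  ifelse(death_age <= exit_age, "death", "censored"))

  out <- data.frame(
    person_id = twins$person_id,
    pair_id = twins$pair_id,
    member_index = twins$member_index,
    sex = twins$sex,
    zygosity = twins$zygosity,
    birth_date = birth,
    entry_age = entry_age,
    exit_age = pmax(exit_age, entry_age),
    exit_cause = cause,
    diagnosis_code = ifelse(cause == "case", code, NA_character_),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$pair_id, out$member_index), ]
  rownames(out) <- NULL
  stopifnot(nrow(out) + sum(ledger) == input_n)
  attr(out, "exclusion_ledger") <- ledger
  attr(out, "dropped_events") <- dropped_events
  class(out) <- c("twin_cohort", "data.frame")
  out
}

#' Exclusion ledger of a built cohort
#'
#' @param cohort A cohort from [build_analysis_cohort()].
#' @return Named integer vector of excluded-individual counts by reason.
#' @export
exclusion_ledger <- function(cohort) {
  attr(cohort, "exclusion_ledger")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
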