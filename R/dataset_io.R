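# Event-dataset I/O in a NONMEM-compatible tabular dialect.
#
# Columns: ID, TIME (h since first dose), AMT (mg), RATE (mg/h),
# EVID (1 dose / 0 observation), DV (mg/L), MDV, CLASS (trough/peak/random),
# then one column per covariate (CRCL, ALT, WT, AGE, SEX, extras...), one
# value per patient. SEX is coded 0 = male, 1 = female.

CORE_COLS <- c("ID", "TIME", "AMT", "RATE", "EVID", "DV", "MDV", "CLASS")
COV_COLS  <- c("CRCL", "ALT", "WT", "AGE", "SEX")

#' Read a pharmacometric event dataset
#'
#' Parses a CSV in the event-record dialect described above into a list of
#' [patient_record()]s. Samples below the total-drug LLOQ are flagged; rows
#' violating the dialect (a DV on a dosing row, an observation before the
#' first dose, non-positive AMT/RATE) are reported with their line numbers.
#'
#' @param path Path to the event CSV.
#' @param config Assay configuration for BLQ flagging.
#' @return A `colipk_study`: list of `patient_record`s.
#' @export
read_dataset <- function(path, config = assay_config()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- setdiff(c("ID", "TIME", "AMT", "RATE", "EVID", "DV", "MDV"),
                  names(df))
  if (length(need))
    stop("missing required columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!"CLASS" %in% names(df)) df$CLASS <- "random"
  df$.line <- seq_len(nrow(df)) + 1L  # header is line 1
  bad <- df$.line[!df$EVID %in% c(0, 1)]
  if (length(bad))
    stop("EVID must be 0 or 1; offending line(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad <- df$.line[df$EVID == 1 & !is.na(df$DV)]
  if (length(bad))
    stop("DV recorded on a dosing (EVID=1) row; line(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad <- df$.line[df$EVID == 1 & (is.na(df$AMT) | df$AMT <= 0 |
                                  is.na(df$RATE) | df$RATE <= 0)]
  if (length(bad))
    stop("dosing rows need positive AMT and RATE; line(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad <- df$.line[df$EVID == 0 & is.na(df$DV)]
  if (length(bad))
    stop("observation rows need a DV; line(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  cov_cols <- setdiff(names(df), c(CORE_COLS, ".line"))
  miss_mand <- setdiff(c("CRCL", "ALT", "WT", "AGE", "SEX"), cov_cols)
  if (length(miss_mand))
    stop("missing covariate columns: ", paste(miss_mand, collapse = ", "),
         call. = FALSE)
  study <- lapply(split(df, factor(df$ID, levels = unique(df$ID))),
                  function(sub) {
    sub <- sub[order(sub$TIME, -sub$EVID), ]
    dose_rows <- sub[sub$EVID == 1, , drop = FALSE]
    obs_rows  <- sub[sub$EVID == 0, , drop = FALSE]
    if (nrow(dose_rows) == 0)
      stop("patient ", sub$ID[1], " has no dose records", call. = FALSE)
    first_dose <- min(dose_rows$TIME)
    bad <- obs_rows$.line[obs_rows$TIME < first_dose]
    if (length(bad))
      stop("observation before first dose; line(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    extras <- list()
    for (cc in setdiff(cov_cols, COV_COLS)) {
      v <- sub[[cc]][1]
      if (!is.na(v)) extras[[tolower(cc)]] <- v
    }
    cov <- covariates(crcl = sub$CRCL[1], alt = sub$ALT[1],
                      weight = sub$WT[1], age = sub$AGE[1],
                      sex = if (sub$SEX[1] == 1) "female" else "male",
                      extras = extras)
    doses <- lapply(seq_len(nrow(dose_rows)), function(i)
      dose_event(dose_rows$TIME[i], dose_rows$AMT[i],
                 dose_rows$AMT[i] / dose_rows$RATE[i]))
    plasma <- lapply(seq_len(nrow(obs_rows)), function(i)
      plasma_sample(obs_rows$TIME[i], obs_rows$DV[i],
                    obs_rows$CLASS[i], config = config))
    patient_record(sub$ID[1], cov, doses, plasma)
  })
  names(study) <- NULL
  structure(study, class = "colipk_study")
}

#' Write a study as an event dataset
#'
#' Inverse of [read_dataset()]: round-trips all fields to full precision.
#'
#' @param study A `colipk_study` (list of `patient_record`s).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(study, path) {
  rows <- lapply(study, function(p) {
    cov <- p$covariates
    covs <- data.frame(CRCL = cov$crcl, ALT = cov$alt, WT = cov$weight,
                       AGE = cov$age,
                       SEX = if (cov$sex == "female") 1 else 0)
    for (nm in names(cov$extras)) covs[[toupper(nm)]] <- cov$extras[[nm]]
    dr <- do.call(rbind, lapply(p$doses, function(d)
      data.frame(ID = p$patient_id, TIME = d$start_time, AMT = d$amount,
                 RATE = d$amount / d$infusion_duration, EVID = 1L,
                 DV = NA_real_, MDV = 1L, CLASS = NA_character_)))
    pr <- if (length(p$plasma))
      do.call(rbind, lapply(p$plasma, function(s)
        data.frame(ID = p$patient_id, TIME = s$time, AMT = NA_real_,
                   RATE = NA_real_, EVID = 0L, DV = s$concentration,
                   MDV = 0L, CLASS = s$sample_class)))
    else NULL
    out <- rbind(dr, pr)
    out <- out[order(out$TIME, -out$EVID), ]
    cbind(out, covs[rep(1, nrow(out)), , drop = FALSE])
  })
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cc in setdiff(all_cols, names(r))) r[[cc]] <- NA
    r[all_cols]
  })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read urine-collection intervals
#'
#' CSV with columns ID, TSTART, TEND, VOLUME_L, CONC_MGL. Intervals are
#' attached to the matching patients of `study` when supplied.
#'
#' @param path Urine CSV path.
#' @param study Optional `colipk_study` to attach intervals to.
#' @return If `study` is `NULL`, a named list of `urine_interval` lists;
#'   otherwise the study with urine attached.
#' @export
read_urine <- function(path, study = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- setdiff(c("ID", "TSTART", "TEND", "VOLUME_L", "CONC_MGL"), names(df))
  if (length(need))
    stop("missing urine columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  by_id <- lapply(split(df, factor(df$ID, levels = unique(df$ID))),
                  function(sub)
    lapply(seq_len(nrow(sub)), function(i)
      urine_interval(sub$TSTART[i], sub$TEND[i], sub$VOLUME_L[i],
                     sub$CONC_MGL[i])))
  if (is.null(study)) return(by_id)
  for (i in seq_along(study)) {
    id <- as.character(study[[i]]$patient_id)
    if (id %in% names(by_id)) study[[i]]$urine <- by_id[[id]]
  }
  study
}

#' Write urine-collection intervals
#' @param study A `colipk_study`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_urine <- function(study, path) {
  rows <- list()
  for (p in study) for (u in p$urine)
    rows[[length(rows) + 1L]] <-
      data.frame(ID = p$patient_id, TSTART = u$start_time, TEND = u$end_time,
                 VOLUME_L = u$volume, CONC_MGL = u$concentration)
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ID = character(), TSTART = numeric(), TEND = numeric(),
               VOLUME_L = numeric(), CONC_MGL = numeric())
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
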