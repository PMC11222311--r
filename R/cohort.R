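# Cohort definition: ICD-code phenotyping, exclusion rules, and RASS/CAM-ICU
# delirium adjudication.

norm_codes <- function(codes) toupper(gsub(".", "", codes, fixed = TRUE))

check_versions <- function(codes, versions) {
  bad <- !(versions %in% c(9, 10))
  if (any(bad)) {
    stop("unknown ICD version for code(s): ",
         paste(codes[bad], collapse = ", "))
  }
}

#' Diabetes mellitus phenotype from ICD codes
#'
#' TRUE iff any ICD-9 diagnosis code starts with 250, or any ICD-10 code
#' starts with E10--E14. Matching is case-insensitive and ignores embedded
#' dots.
#'
#' @param codes Character vector of diagnosis codes.
#' @param versions Integer vector (9 or 10), recycled if length 1.
#' @return Logical scalar.
#' @examples
#' is_dm(c("25000"), 9)
#' is_dm(c("E11.65"), 10)
#' @export
is_dm <- function(codes, versions) {
  if (length(codes) == 0) return(FALSE)
  versions <- rep_len(versions, length(codes))
  check_versions(codes, versions)
  codes <- norm_codes(codes)
  any(versions == 9 & startsWith(codes, "250")) ||
    any(versions == 10 &
          Reduce(`|`, lapply(paste0("E1", 0:4), startsWith, x = codes)))
}

#' Coronary artery bypass grafting phenotype from ICD procedure codes
#'
#' TRUE iff any ICD-9 procedure code starts with 3611--3619 or 362, or any
#' ICD-10-PCS code starts with 0210--0213. "362" is treated as a prefix so
#' that its subcodes match. Case-insensitive, dots ignored.
#'
#' @inheritParams is_dm
#' @return Logical scalar.
#' @export
is_cabg <- function(codes, versions) {
  if (length(codes) == 0) return(FALSE)
  versions <- rep_len(versions, length(codes))
  check_versions(codes, versions)
  codes <- norm_codes(codes)
  icd9_pref <- c(paste0("361", 1:9), "362")
  icd10_pref <- paste0("021", 0:3)
  any(versions == 9 &
        Reduce(`|`, lapply(icd9_pref, startsWith, x = codes))) ||
    any(versions == 10 &
          Reduce(`|`, lapply(icd10_pref, startsWith, x = codes)))
}

# Exclusion rules in adjudication order; a record failing several is logged
# once, under the first that fires.
EXCLUSION_RULES <- c(
  "age<18", "icu_los<24h", "coma_or_delirium_24h",
  "neuropsychiatric_comorbidity", "alcohol_drug_abuse", "repeat_admission"
)

NEURO_FLAGS <- c("dementia", "psychoses", "tbi", "reading_disorder",
                 "intellectual_disability", "neurological_disease")

#' Apply the study exclusion criteria
#'
#' Drops records with age < 18 years; ICU stay under 24 h; coma or delirium
#' within the first 24 h; any of dementia, psychoses, traumatic brain injury,
#' reading disorder, intellectual disability, or neurological disease;
#' alcohol/drug abuse; and all but the first admission per patient. Rules are
#' evaluated in that order and each excluded record is logged once under the
#' first rule that fired.
#'
#' @param records Data frame with columns `patient_id`, `admission_index`,
#'   `age`, `icu_los_hours`, the logical flag `coma_or_delirium_24h`, flags
#'   `dementia`, `psychoses`, `tbi`, `reading_disorder`,
#'   `intellectual_disability`, `neurological_disease`, and
#'   `alcohol_drug_abuse`.
#' @return List with `kept` (data frame of retained records) and `log`
#'   (data frame `patient_id`, `admission_index`, `rule`).
#' @export
apply_exclusions <- function(records) {
  req <- c("patient_id", "admission_index", "age", "icu_los_hours",
           "coma_or_delirium_24h", NEURO_FLAGS, "alcohol_drug_abuse")
  for (f in req) {
    if (!f %in% names(records)) stop("missing required field: ", f)
    if (anyNA(records[[f]])) {
      bad <- records$patient_id[is.na(records[[f]])][1]
      stop("missing value in field '", f, "' for patient ", bad)
    }
  }
  rule <- rep(NA_character_, nrow(records))
  hit <- function(cond, name) ifelse(is.na(rule) & cond, name, rule)
  rule <- hit(records$age < 18, "age<18")
  rule <- hit(records$icu_los_hours < 24, "icu_los<24h")
  rule <- hit(as.logical(records$coma_or_delirium_24h),
              "coma_or_delirium_24h")
  neuro <- Reduce(`|`, lapply(NEURO_FLAGS, function(f)
    as.logical(records[[f]])))
  rule <- hit(neuro, "neuropsychiatric_comorbidity")
  rule <- hit(as.logical(records$alcohol_drug_abuse), "alcohol_drug_abuse")
  rule <- hit(records$admission_index != 1, "repeat_admission")
  excl <- !is.na(rule)
  list(
    kept = records[!excl, , drop = FALSE],
    log = data.frame(patient_id = records$patient_id[excl],
                     admission_index = records$admission_index[excl],
                     rule = rule[excl], stringsAsFactors = FALSE)
  )
}

#' Adjudicate delirium from a RASS score and CAM-ICU features
#'
#' A RASS score below -3 marks the patient comatose and ineligible for
#' CAM-ICU assessment (RASS of exactly -3 remains eligible). Otherwise the
#' patient is delirious iff CAM-ICU Features 1 (altered level of
#' consciousness) and 2 (mental status change) are both positive together
#' with Feature 3 (inattention) or Feature 4 (disorganized thinking).
#'
#' @param rass Integer RASS score in -5..4 (vectorized).
#' @param feature1,feature2,feature3,feature4 Logical CAM-ICU features.
#' @return Character vector: `"delirium"`, `"no_delirium"`, or
#'   `"coma_ineligible"`.
#' @export
adjudicate_delirium <- function(rass, feature1, feature2, feature3,
                                feature4) {
  if (any(rass < -5 | rass > 4)) stop("RASS score out of range [-5, 4]")
  ifelse(rass < -3, "coma_ineligible",
         ifelse(feature1 & feature2 & (feature3 | feature4),
                "delirium", "no_delirium"))
}

#' Build the analysis cohort from raw records (and optional assessments)
#'
#' Convenience wrapper: applies DM/CABG phenotyping when code columns are
#' present (semicolon-delimited `diagnosis_codes`/`procedure_codes` with
#' matching `*_versions`), runs [apply_exclusions()], and, when a long-format
#' assessment table is supplied, adjudicates the delirium outcome as
#' "delirious at any eligible assessment".
#'
#' @param records Record data frame (see [apply_exclusions()]).
#' @param assessments Optional data frame with `patient_id`, `rass`,
#'   `feature1`..`feature4`.
#' @param require_phenotype If TRUE and code columns exist, drop records not
#'   meeting both the DM and CABG definitions (logged as
#'   `"phenotype_mismatch"` before the standard rules).
#' @return List with `kept`, `log`, and (when assessments given) `kept$pod`
#'   filled in.
#' @export
build_cohort <- function(records, assessments = NULL,
                         require_phenotype = FALSE) {
  log0 <- NULL
  if (require_phenotype &&
      all(c("diagnosis_codes", "diagnosis_versions",
            "procedure_codes", "procedure_versions") %in% names(records))) {
    split_ <- function(x) strsplit(as.character(x), ";", fixed = TRUE)
    dg <- split_(records$diagnosis_codes)
    dv <- lapply(split_(records$diagnosis_versions), as.integer)
    pg <- split_(records$procedure_codes)
    pv <- lapply(split_(records$procedure_versions), as.integer)
    ok <- vapply(seq_len(nrow(records)), function(i)
      is_dm(dg[[i]], dv[[i]]) && is_cabg(pg[[i]], pv[[i]]), logical(1))
    log0 <- data.frame(patient_id = records$patient_id[!ok],
                       admission_index = records$admission_index[!ok],
                       rule = "phenotype_mismatch",
                       stringsAsFactors = FALSE)
    records <- records[ok, , drop = FALSE]
  }
  res <- apply_exclusions(records)
  if (!is.null(log0)) res$log <- rbind(log0, res$log)
  if (!is.null(assessments)) {
    verdicts <- adjudicate_delirium(assessments$rass, assessments$feature1,
                                    assessments$feature2,
                                    assessments$feature3,
                                    assessments$feature4)
    pod_ids <- unique(assessments$patient_id[verdicts == "delirium"])
    res$kept$pod <- as.integer(res$kept$patient_id %in% pod_ids)
  }
  res
}
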