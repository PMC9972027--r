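## Post-screen candidate triage: configurable flag -> reason exclusion
## rules applied to confirmed hits. Exclusion criteria are data, not code,
## so the engine is reusable for other screens.

#' Default exclusion rules
#'
#' Two rules mirroring common post-screen expert judgments: a compound
#' whose drug class is already in clinical use for the disease
#' (topoisomerase inhibitors, for choriocarcinoma) is excluded as
#' redundant, and cardiac glycosides are excluded for potential cardiac
#' adverse events.
#'
#' @return data.frame with columns `flag` and `reason`, evaluated in row
#'   order (first matching flag wins).
#' @export
#' @examples
#' defaultExclusionRules()
defaultExclusionRules <- function() {
    data.frame(
        flag = c("topoisomerase_class", "cardiac_glycoside_class"),
        reason = c("class_in_clinical_use", "cardiac_toxicity_class"),
        stringsAsFactors = FALSE)
}

#' Apply exclusion rules to confirmed hits
#'
#' Evaluates the rules in declared order against each hit's annotation
#' flags; the first matching rule excludes the compound with its reason,
#' and unmatched hits become candidates (`reason = "none"`). Every hit
#' must have an annotation row.
#'
#' @param hitIds character vector of confirmed-hit compound ids.
#' @param annotations annotation data.frame (see
#'   [readCompoundAnnotations()]).
#' @param rules data.frame of `flag`/`reason` pairs; defaults to
#'   [defaultExclusionRules()].
#' @return data.frame with one row per hit: `compound_id`, `status`
#'   (`candidate`/`excluded`), `reason`, `flags`.
#' @export
#' @examples
#' ann <- data.frame(
#'     compound_id = c("vorinostat", "topotecan", "digoxin"),
#'     name = c("vorinostat", "topotecan", "digoxin"),
#'     category = c("oncology", "oncology", "cardiovascular"),
#'     flags = c("", "topoisomerase_class", "cardiac_glycoside_class"))
#' applyExclusionRules(ann$compound_id, ann)
applyExclusionRules <- function(hitIds, annotations,
                                rules = defaultExclusionRules()) {
    stopifnot(is.data.frame(rules),
        all(c("flag", "reason") %in% names(rules)))
    missing <- setdiff(hitIds, annotations$compound_id)
    if (length(missing))
        stop("missing annotation for hit ", missing[1])
    fl <- annotationFlags(annotations)
    decide <- function(cid) {
        flags <- fl[[cid]]
        for (i in seq_len(nrow(rules))) {
            if (rules$flag[i] %in% flags)
                return(c("excluded", rules$reason[i]))
        }
        c("candidate", "none")
    }
    dec <- t(vapply(hitIds, decide, character(2)))
    data.frame(
        compound_id = hitIds,
        status = unname(dec[, 1]),
        reason = unname(dec[, 2]),
        flags = vapply(fl[hitIds], paste, character(1), collapse = ";"),
        stringsAsFactors = FALSE, row.names = NULL)
}

#' Count compounds per therapeutic category
#'
#' @param compoundIds compound ids to tabulate (each must be annotated).
#' @param annotations annotation data.frame.
#' @return data.frame with columns `category` and `n` (descending counts,
#'   ties broken alphabetically); counts sum to `length(compoundIds)`.
#' @export
summarizeCategories <- function(compoundIds, annotations) {
    if (!length(compoundIds))
        return(data.frame(category = character(0), n = integer(0)))
    missing <- setdiff(compoundIds, annotations$compound_id)
    if (length(missing))
        stop("missing annotation for compound ", missing[1])
    cat <- annotations$category[match(compoundIds, annotations$compound_id)]
    tab <- table(cat)
    out <- data.frame(category = names(tab), n = as.integer(tab),
        stringsAsFactors = FALSE)
    out[order(-out$n, out$category), , drop = FALSE]
}
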