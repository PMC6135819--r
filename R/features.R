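#' Nucleus-level feature vector from nuclear and nucleolar signatures
#'
#' Merges nucleolus-level morphometry into the parent nucleus record by
#' computing sample statistics (average, minimum, maximum, variance) of each
#' of the six measures across the nucleolar list, so that every nucleus
#' yields a feature vector of the same length regardless of its nucleolus
#' count: 6 nuclear measures + NucleolusCount + 4 x 6 nucleolar aggregates =
#' 31 features. Variance is the sample variance (n - 1 denominator), 0 for a
#' single nucleolus.
#'
#' @param nucleus_sig one-row [compute_signature()] result for the nucleus.
#' @param nucleolar_sigs non-empty list of signatures for its nucleoli
#'   (nuclei without nucleoli must be excluded upstream).
#' @return A one-row data.frame: `image_id`, `condition`, `object_id`, the 6
#'   nuclear measures, `NucleolusCount`, and `Avg`/`Min`/`Max`/`Var`-prefixed
#'   nucleolar columns.
#' @export
aggregate_features <- function(nucleus_sig, nucleolar_sigs) {
  if (length(nucleolar_sigs) < 1)
    stop("a nucleus must have at least one nucleolus (excluded upstream)")
  nucl <- do.call(rbind, lapply(nucleolar_sigs, as.data.frame))
  rec <- data.frame(image_id = nucleus_sig$image_id,
                    condition = nucleus_sig$condition,
                    object_id = nucleus_sig$object_id,
                    stringsAsFactors = FALSE)
  for (m in signature_measures) rec[[m]] <- nucleus_sig[[m]]
  rec$NucleolusCount <- nrow(nucl)
  for (m in signature_measures) {
    x <- nucl[[m]]
    rec[[paste0("Avg", m)]] <- mean(x)
    rec[[paste0("Min", m)]] <- min(x)
    rec[[paste0("Max", m)]] <- max(x)
    rec[[paste0("Var", m)]] <- if (length(x) > 1) stats::var(x) else 0
  }
  rec
}

#' Names of the 31 classification features
#'
#' @return Character vector: the 6 nuclear measures, `NucleolusCount`, and
#'   the 24 `Avg`/`Min`/`Max`/`Var` nucleolar aggregates.
#' @export
feature_names <- function() {
  c(signature_measures, "NucleolusCount",
    as.vector(t(outer(c("Avg", "Min", "Max", "Var"), signature_measures,
                      paste0))))
}

#' Assemble nucleus records into a feature table
#'
#' @param records list of one-row data.frames from [aggregate_features()].
#' @return A data.frame with columns `image_id`, `condition`, `object_id`
#'   and the 31 features in stable order; zero rows (with full header) for
#'   an empty list.
#' @export
build_feature_table <- function(records) {
  cols <- c("image_id", "condition", "object_id", feature_names())
  if (length(records) == 0) {
    out <- as.data.frame(stats::setNames(
      c(list(character(0), character(0), integer(0)),
        rep(list(numeric(0)), length(feature_names()))), cols))
    return(out)
  }
  tab <- do.call(rbind, records)
  if (anyDuplicated(paste(tab$image_id, tab$object_id)) > 0)
    stop("duplicated object ids in feature records")
  if (anyNA(tab[, feature_names()]))
    stop("missing values in feature table")
  tab[, cols]
}
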