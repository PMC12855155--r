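# Group-level and genus-level aggregation of selection partitions across
# timepoints.

prop_from_labels <- function(labels) {
  tab <- table(factor(labels, levels = c("above", "neutral", "below")))
  as.numeric(tab) / sum(tab)
}

#' Format a cross-timepoint percentage range
#'
#' Renders a min-max range of proportions as the study's reporting style,
#' e.g. `"20.4%-28.2%"` with one decimal place.
#'
#' @param props numeric proportions in \[0, 1\].
#' @return a single range string.
#' @export
format_range <- function(props) {
  props <- props[!is.na(props)]
  if (!length(props)) return(NA_character_)
  sprintf("%.1f%%–%.1f%%", 100 * min(props), 100 * max(props))
}

#' Group-level selection proportions across timepoints
#'
#' Computes, for each timepoint's partition table, the fractions of
#' fitted SGBs labelled above / neutral / below, and the min-max range of
#' each fraction across timepoints.
#'
#' @param tables named list of `ncm_partition` tables, one per timepoint.
#' @return object of class `selection_summary`: list with `unit`
#'   ("group"), `per_timepoint` (data frame: timepoint, n_sgb,
#'   prop_above, prop_neutral, prop_below) and `ranges` (named range
#'   strings).
#' @export
partition_proportions <- function(tables) {
  if (!length(tables)) stop("no partition tables supplied", call. = FALSE)
  if (is.null(names(tables)))
    names(tables) <- paste0("T", seq_along(tables))
  per <- do.call(rbind, lapply(names(tables), function(tp) {
    tab <- tables[[tp]]
    if (!nrow(tab)) stop("empty partition table for ", tp, call. = FALSE)
    pr <- prop_from_labels(tab$label)
    data.frame(timepoint = tp, n_sgb = nrow(tab),
               prop_above = pr[1], prop_neutral = pr[2],
               prop_below = pr[3], stringsAsFactors = FALSE)
  }))
  structure(list(
    unit = "group",
    per_timepoint = per,
    ranges = c(above = format_range(per$prop_above),
               neutral = format_range(per$prop_neutral),
               below = format_range(per$prop_below))
  ), class = "selection_summary")
}

#' Genus-level selection proportions and ranges
#'
#' For each requested genus, computes the above/neutral/below fractions
#' among that genus's fitted SGBs at each timepoint (denominator = fitted
#' SGBs of the genus at that timepoint) and the min-max range across the
#' timepoints where the genus is present.  A genus absent from a
#' timepoint's fit set is marked absent there (NA), not zero; a genus
#' matching no SGBs anywhere is dropped with a warning.
#'
#' @param tables named list of `ncm_partition` tables, one per timepoint.
#' @param taxonomy validated taxonomy table (with `genus` column; see
#'   [read_taxonomy()]).
#' @param genera character vector of genus names (GTDB genus token
#'   without the `g__` prefix, e.g. `"Fibrobacter"`).
#' @return object of class `selection_summary`: list with `unit`
#'   ("genus"), `per_timepoint` (data frame: genus, timepoint, n_sgb,
#'   prop_above, prop_neutral, prop_below, present) and `ranges` (data
#'   frame: genus, range_above, range_neutral, range_below,
#'   n_timepoints_present).
#' @export
taxon_selection_ranges <- function(tables, taxonomy, genera) {
  if (!length(tables)) stop("no partition tables supplied", call. = FALSE)
  if (is.null(names(tables)))
    names(tables) <- paste0("T", seq_along(tables))
  if (!"genus" %in% colnames(taxonomy))
    taxonomy <- validate_taxonomy(taxonomy)
  genera <- sub("^g__", "", genera)

  rows <- list(); ranges <- list()
  for (g in genera) {
    ids <- taxonomy$sgb_id[taxonomy$genus == g]
    present_any <- FALSE
    per <- list()
    for (tp in names(tables)) {
      tab <- tables[[tp]]
      sub <- tab[tab$sgb_id %in% ids, , drop = FALSE]
      if (nrow(sub)) {
        present_any <- TRUE
        pr <- prop_from_labels(sub$label)
        per[[tp]] <- data.frame(genus = g, timepoint = tp,
                                n_sgb = nrow(sub), prop_above = pr[1],
                                prop_neutral = pr[2], prop_below = pr[3],
                                present = TRUE, stringsAsFactors = FALSE)
      } else {
        per[[tp]] <- data.frame(genus = g, timepoint = tp, n_sgb = 0L,
                                prop_above = NA_real_,
                                prop_neutral = NA_real_,
                                prop_below = NA_real_, present = FALSE,
                                stringsAsFactors = FALSE)
      }
    }
    if (!present_any) {
      warning("genus ", g, " matches no fitted SGBs in any table; omitted")
      next
    }
    per <- do.call(rbind, per)
    rows[[g]] <- per
    ranges[[g]] <- data.frame(
      genus = g,
      range_above = format_range(per$prop_above),
      range_neutral = format_range(per$prop_neutral),
      range_below = format_range(per$prop_below),
      n_timepoints_present = sum(per$present),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop("none of the requested genera match any fitted SGB",
         call. = FALSE)
  structure(list(
    unit = "genus",
    per_timepoint = do.call(rbind, c(rows, list(make.row.names = FALSE))),
    ranges = do.call(rbind, c(ranges, list(make.row.names = FALSE)))
  ), class = "selection_summary")
}

#' @export
print.selection_summary <- function(x, ...) {
  cat("Selection summary (", x$unit, " level)\n", sep = "")
  if (x$unit == "group") {
    print(x$per_timepoint, row.names = FALSE)
    cat(sprintf("  above %s, neutral %s, below %s across timepoints\n",
                x$ranges["above"], x$ranges["neutral"],
                x$ranges["below"]))
  } else {
    print(x$ranges, row.names = FALSE)
  }
  invisible(x)
}
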