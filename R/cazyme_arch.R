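# Parsing of CAZyme domain-architecture strings, tandem-CBM run
# detection, and per-genome counts of CBM-associated catalytic enzyme
# structures.

CATALYTIC_CLASSES <- c("GH", "PL", "CE", "AA")
# a complete domain token: 2-4 letter class code + family number +
# optional subfamily ("CBM11", "GH43_16"); hyphens split only between two
# of these, so "GH43_16" or free-text labels are never broken up
DOMAIN_TOKEN_RE <- "^[A-Za-z]{2,4}[0-9]+(_[0-9]+)?$"

classify_token <- function(tokens, catalytic = CATALYTIC_CLASSES) {
  cls <- rep("other", length(tokens))
  cls[grepl("^CBM[0-9]", tokens)] <- "CBM"
  pat <- paste0("^(", paste(catalytic, collapse = "|"), ")[0-9]")
  cls[grepl(pat, tokens)] <- "catalytic"
  cls
}

#' Family of a domain token
#'
#' Strips a subfamily suffix: `GH43_16` -> `GH43`, `CBM6` -> `CBM6`.
#'
#' @param tokens character vector of domain labels.
#' @return character vector of family labels.
#' @export
domain_family <- function(tokens) sub("_[0-9]+$", "", tokens)

#' Parse a domain-architecture string
#'
#' Splits an ordered architecture string such as
#' `"CBM11+CBM11+CBM11+GH51"` into domain tokens and classifies each as
#' CBM, catalytic (GH/PL/CE/AA by default) or other.  `+` and `|` always
#' delimit; `-` delimits only between two complete domain tokens, so
#' subfamily labels like `GH43_16` are never split and hyphen-written
#' architectures like `CBM11-CBM11-CBM11` parse correctly.
#'
#' @param raw non-empty architecture string.
#' @param catalytic prefixes counted as catalytic classes (default GH,
#'   PL, CE, AA; add `"GT"` to include glycosyltransferases).
#' @return list of class `domain_architecture` with `tokens` (ordered
#'   labels) and `classes` (matching classification vector).
#' @export
parse_architecture <- function(raw, catalytic = CATALYTIC_CLASSES) {
  if (!is.character(raw) || length(raw) != 1L || !nzchar(trimws(raw)))
    stop("architecture string must be non-empty", call. = FALSE)
  pieces <- strsplit(raw, "[+|]")[[1L]]
  tokens <- unlist(lapply(pieces, function(x) {
    x <- trimws(x)
    if (!nzchar(x)) return(character())
    sub <- strsplit(x, "-", fixed = TRUE)[[1L]]
    # hyphens split only when every flank is itself a complete token
    if (length(sub) > 1L && all(grepl(DOMAIN_TOKEN_RE, trimws(sub))))
      trimws(sub)
    else x
  }))
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens))
    stop("architecture \"", raw, "\" is empty after parsing",
         call. = FALSE)
  structure(list(tokens = tokens,
                 classes = classify_token(tokens, catalytic)),
            class = "domain_architecture")
}

#' Detect tandem CBM runs
#'
#' Finds maximal runs of consecutive CBM-class tokens of length
#' `>= min_run`, left to right.
#'
#' @param arch `domain_architecture` from [parse_architecture()].
#' @param min_run minimum run length (default 2).
#' @return data frame with 0-based `start` and `length` per run.
#' @export
detect_tandem_cbms <- function(arch, min_run = 2) {
  stopifnot(inherits(arch, "domain_architecture"))
  r <- rle(arch$classes == "CBM")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  data.frame(start = starts[keep] - 1L, length = r$lengths[keep])
}

#' Per-genome CBM-structure profile
#'
#' A "CBM-associated catalytic enzyme structure" is a protein that
#' carries at least one CBM domain and at least one catalytic domain
#' (counted once per protein).  The profile also records the longest
#' tandem CBM run, a histogram of tandem-run lengths (length >= 2), and
#' the distinct CBM and catalytic families among qualifying proteins.
#'
#' @param archs data frame with columns `protein_id`, `genome_id`,
#'   `architecture` — all rows from one genome.
#' @param catalytic catalytic class prefixes (see
#'   [parse_architecture()]).
#' @param unit `"protein"` (default: one count per qualifying protein)
#'   or `"adjacency"` (count of adjacent CBM-catalytic domain pairs,
#'   the alternative reading of a structure count).
#' @return list of class `genome_cbm_profile` with `genome_id`,
#'   `n_proteins`, `n_cbm_structures`, `max_tandem_run`,
#'   `tandem_run_histogram`, `cbm_families`, `catalytic_families`.
#' @export
count_cbm_structures <- function(archs, catalytic = CATALYTIC_CLASSES,
                                 unit = c("protein", "adjacency")) {
  unit <- match.arg(unit)
  if (nrow(archs)) {
    gid <- unique(archs$genome_id)
    if (length(gid) != 1L)
      stop("count_cbm_structures expects a single genome; got: ",
           paste(gid, collapse = ", "), call. = FALSE)
  } else gid <- NA_character_

  n_struct <- 0L
  max_run <- 0L
  run_lengths <- integer()
  cbm_fam <- character(); cat_fam <- character()
  for (i in seq_len(nrow(archs))) {
    arch <- parse_architecture(archs$architecture[i], catalytic)
    has_cbm <- any(arch$classes == "CBM")
    has_cat <- any(arch$classes == "catalytic")
    if (has_cbm) {
      r <- rle(arch$classes == "CBM")
      max_run <- max(max_run, max(r$lengths[r$values]))
      run_lengths <- c(run_lengths,
                       r$lengths[r$values & r$lengths >= 2L])
    }
    if (has_cbm && has_cat) {
      if (unit == "protein") {
        n_struct <- n_struct + 1L
      } else {
        adj <- sum((arch$classes[-1L] == "CBM" &
                      arch$classes[-length(arch$classes)] == "catalytic") |
                     (arch$classes[-1L] == "catalytic" &
                        arch$classes[-length(arch$classes)] == "CBM"))
        n_struct <- n_struct + adj
      }
      cbm_fam <- c(cbm_fam,
                   domain_family(arch$tokens[arch$classes == "CBM"]))
      cat_fam <- c(cat_fam,
                   domain_family(arch$tokens[arch$classes == "catalytic"]))
    }
  }
  structure(list(
    genome_id = gid,
    n_proteins = nrow(archs),
    n_cbm_structures = n_struct,
    max_tandem_run = max_run,
    tandem_run_histogram = if (length(run_lengths)) table(run_lengths)
                           else table(integer()),
    cbm_families = sort(unique(cbm_fam)),
    catalytic_families = sort(unique(cat_fam))
  ), class = "genome_cbm_profile")
}

#' Profile every genome in a domain-architecture table
#'
#' @param table data frame with columns `protein_id`, `genome_id`,
#'   `architecture`.
#' @param ... passed to [count_cbm_structures()].
#' @return named list of `genome_cbm_profile` objects.
#' @export
profile_genomes <- function(table, ...) {
  need <- c("protein_id", "genome_id", "architecture")
  miss <- setdiff(need, colnames(table))
  if (length(miss))
    stop("architecture table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  by_genome <- split(table, table$genome_id)
  lapply(by_genome, count_cbm_structures, ...)
}

#' Compare CBM-structure counts between genome groups
#'
#' Summarizes `n_cbm_structures` per group (median, IQR) and reports the
#' pairwise fold difference of medians; for the two-group case a
#' Mann-Whitney (Wilcoxon rank-sum) p-value is attached.
#'
#' @param profiles list of `genome_cbm_profile` objects.
#' @param groups named character vector mapping genome_id to group.
#' @return list with `summary` (data frame: group, n_genomes, median,
#'   q25, q75), `fold_difference` (data frame of pairwise median ratios)
#'   and `p_value` (two-group Mann-Whitney, else NA).
#' @export
genome_cbm_ranking <- function(profiles, groups) {
  counts <- vapply(profiles, `[[`, numeric(1L), "n_cbm_structures")
  ids <- vapply(profiles, `[[`, character(1L), "genome_id")
  grp <- groups[ids]
  if (any(is.na(grp)))
    stop("genomes without a group assignment: ",
         paste(ids[is.na(grp)], collapse = ", "), call. = FALSE)
  levels <- unique(grp)
  empty <- setdiff(unique(groups), levels)
  if (length(empty))
    warning("group(s) with 0 genomes omitted: ",
            paste(empty, collapse = ", "))
  if (length(levels) < 2L)
    stop("need >= 2 non-empty groups to rank", call. = FALSE)
  summ <- do.call(rbind, lapply(levels, function(g) {
    x <- counts[grp == g]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7)
    data.frame(group = g, n_genomes = length(x), median = unname(q[2L]),
               q25 = unname(q[1L]), q75 = unname(q[3L]),
               stringsAsFactors = FALSE)
  }))
  pairs <- utils::combn(levels, 2L)
  fold <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    ma <- summ$median[summ$group == a]; mb <- summ$median[summ$group == b]
    data.frame(group_a = a, group_b = b,
               fold_difference = if (mb > 0) ma / mb else Inf,
               stringsAsFactors = FALSE)
  }))
  p <- NA_real_
  if (length(levels) == 2L)
    p <- suppressWarnings(stats::wilcox.test(
      counts[grp == levels[1L]], counts[grp == levels[2L]]))$p.value
  list(summary = summ, fold_difference = fold, p_value = p)
}
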