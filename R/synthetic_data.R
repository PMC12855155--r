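# Seeded generators emulating the study design: a two-diet, two-efficiency,
# four-timepoint cattle feeding trial with ~10 animals per feed-efficiency
# group per timepoint, long-tailed SGB metacommunities, Beta-distributed
# local abundances under neutrality, injected selected taxa, and
# dbCAN-style domain-architecture tables.

#' Simulate one neutral group-timepoint slice
#'
#' Inverts the Sloan model as a generator: a long-tailed metacommunity
#' profile p is drawn from a lognormal (sigma = `abundance_shape`) and
#' normalized; for each SGB i and animal j a local relative abundance is
#' drawn from Beta(Nm_true * p_i, Nm_true * (1 - p_i)); each animal's
#' abundance vector is renormalized to sum one; sequencing depth per
#' animal is Poisson(`depth_mean`) and counts are multinomial at that
#' depth.  All randomness flows through the single `seed`.
#'
#' @param n_sgb number of SGBs (>= 1).
#' @param n_animals number of animals / samples (>= 2).
#' @param Nm_true effective immigration parameter generating the slice.
#' @param depth_mean expected reads per sample.
#' @param abundance_shape lognormal sigma of the metacommunity profile
#'   (default 2, long-tailed like real SGB profiles).
#' @param seed integer seed; identical parameters + seed reproduce the
#'   matrix bit-for-bit.
#' @param sgb_ids,sample_ids optional identifier vectors.
#' @param p_meta optional metacommunity profile (sums to 1), overriding
#'   the lognormal draw so that slices of a study can share one
#'   metacommunity.
#' @return list with `counts` (count matrix) and `truth` (list recording
#'   `Nm_true`, `p_meta`, `selected_above`, `selected_below`,
#'   `depth_mean`, `seed`).
#' @export
simulate_neutral_slice <- function(n_sgb, n_animals, Nm_true,
                                   depth_mean = 1e5, abundance_shape = 2,
                                   seed = 1L,
                                   sgb_ids = NULL, sample_ids = NULL,
                                   p_meta = NULL) {
  if (n_sgb < 1) stop("n_sgb must be >= 1", call. = FALSE)
  if (n_animals < 2) stop("n_animals must be >= 2", call. = FALSE)
  if (!is.finite(Nm_true) || Nm_true <= 0)
    stop("Nm_true must be positive", call. = FALSE)
  if (is.null(sgb_ids))
    sgb_ids <- sprintf("SGB%04d", seq_len(n_sgb))
  if (is.null(sample_ids))
    sample_ids <- sprintf("S%03d", seq_len(n_animals))
  stopifnot(length(sgb_ids) == n_sgb, length(sample_ids) == n_animals)

  counts <- withr::with_seed(seed, {
    if (is.null(p_meta)) {
      raw <- stats::rlnorm(n_sgb, meanlog = 0, sdlog = abundance_shape)
      p_meta <- raw / sum(raw)
    } else {
      stopifnot(length(p_meta) == n_sgb)
      if (abs(sum(p_meta) - 1) > 1e-12)
        stop("p_meta must sum to 1", call. = FALSE)
    }
    alpha <- Nm_true * p_meta
    if (any(alpha == 0))
      stop("Nm_true * p underflows to 0 for some SGB; ",
           "increase Nm_true or reduce n_sgb", call. = FALSE)
    depth <- stats::rpois(n_animals, depth_mean)
    m <- matrix(0L, nrow = n_sgb, ncol = n_animals,
                dimnames = list(sgb_ids, sample_ids))
    for (j in seq_len(n_animals)) {
      if (n_sgb == 1L) {
        x <- 1
      } else {
        x <- stats::rbeta(n_sgb, alpha, Nm_true * (1 - p_meta))
        s <- sum(x)
        x <- if (s > 0) x / s else rep(1 / n_sgb, n_sgb)
      }
      m[, j] <- stats::rmultinom(1L, size = depth[j], prob = x)[, 1L]
    }
    m
  })
  truth <- list(Nm_true = Nm_true, p_meta = p_meta,
                selected_above = character(), selected_below = character(),
                depth_mean = depth_mean, seed = seed)
  list(counts = counts, truth = truth)
}

#' Inject positively and negatively selected taxa into a neutral slice
#'
#' Positive selection is emulated by forcing detection: `n_above` SGBs
#' from the bottom abundance tercile (where neutral occupancy is low)
#' receive at least one read in every animal.  Negative selection is
#' emulated by suppression: `n_below` SGBs from the middle tercile are
#' zeroed in a random majority (>= 60%, < 100%) of animals.  Only the
#' targeted rows change, and the reads added or removed stay under 1% of
#' every column total.
#'
#' @param counts count matrix from [simulate_neutral_slice()].
#' @param truth matching truth record.
#' @param n_above,n_below numbers of taxa to push above / below
#'   neutrality.
#' @param seed integer seed for target choice.
#' @param above_ids,below_ids optional preselected target SGB
#'   identifiers (overriding the random choice and `n_above`/`n_below`),
#'   so the same taxa can stay under selection across the timepoints of
#'   a study.
#' @return list with modified `counts` and updated `truth`
#'   (`selected_above`, `selected_below` filled in).
#' @export
inject_selection <- function(counts, truth, n_above, n_below, seed = 1L,
                             above_ids = NULL, below_ids = NULL) {
  validate_count_matrix(counts)
  n_sgb <- nrow(counts)
  n_animals <- ncol(counts)
  if (!is.null(above_ids)) n_above <- length(above_ids)
  if (!is.null(below_ids)) n_below <- length(below_ids)
  if (n_above + n_below > n_sgb)
    stop("n_above + n_below exceeds the number of SGBs", call. = FALSE)
  if (n_above == 0 && n_below == 0) return(list(counts = counts,
                                                truth = truth))
  p <- truth$p_meta
  terc <- cut(rank(p, ties.method = "first"),
              breaks = 3, labels = c("low", "mid", "high"))
  col_tot <- colSums(counts)
  budget <- 0.01 * min(col_tot)
  # each above-taxon adds at most 1 read per column
  if (n_above >= budget)
    stop("injection would perturb a column total by >= 1%", call. = FALSE)

  withr::with_seed(seed, {
    if (is.null(above_ids)) {
      lo <- which(terc == "low")
      if (length(lo) < n_above)
        stop("not enough low-abundance SGBs to inject ", n_above,
             " above-type taxa", call. = FALSE)
      above <- if (n_above > 0) sample(lo, n_above) else integer()
    } else {
      above <- match(above_ids, rownames(counts))
      if (anyNA(above)) stop("unknown above_ids", call. = FALSE)
    }
    for (i in above) {
      zero <- counts[i, ] == 0
      counts[i, zero] <- 1L
    }
    # below candidates: mid tercile, small enough that zeroing all of
    # them together stays under the 1% per-column budget
    cap <- 0.01 * col_tot / max(1L, n_below)
    if (is.null(below_ids)) {
      mid <- which(terc == "mid")
      mid <- setdiff(mid, above)
      ok <- mid[apply(counts[mid, , drop = FALSE], 1L,
                      function(r) all(r < cap))]
      if (length(ok) < n_below)
        stop("not enough eligible mid-abundance SGBs to inject ", n_below,
             " below-type taxa", call. = FALSE)
      below <- sample(ok, n_below)
    } else {
      below <- match(below_ids, rownames(counts))
      if (anyNA(below)) stop("unknown below_ids", call. = FALSE)
      removed <- colSums(counts[below, , drop = FALSE])
      if (any(removed >= 0.01 * col_tot))
        stop("preselected below_ids would perturb a column total by >= 1%",
             call. = FALSE)
    }
    k_min <- ceiling(0.6 * n_animals)
    for (i in below) {
      k <- if (k_min >= n_animals - 1L) k_min
           else sample(k_min:(n_animals - 1L), 1L)
      counts[i, sample(n_animals, min(k, n_animals))] <- 0L
    }
    truth$selected_above <- rownames(counts)[above]
    truth$selected_below <- rownames(counts)[below]
  })
  list(counts = counts, truth = truth)
}

#' Simulate a full longitudinal feeding-trial study
#'
#' Builds one count matrix spanning all (feed-efficiency group x
#' timepoint) cells of a design like the study's: the two groups share a
#' single lognormal metacommunity, each group has its own Nm, animals
#' keep their identifiers across timepoints, and selected taxa
#' (injected per group at every timepoint) are concentrated in designated
#' genera so that genus-level selection summaries have a known answer.
#'
#' @param n_animals_per_cell animals per feed-efficiency group (default
#'   10, the study's per-timepoint group size).
#' @param timepoints character vector of timepoints (default the study's
#'   D1, D80, D100, D180).
#' @param n_sgb number of SGBs.
#' @param Nm_by_group named list/vector of per-group Nm, names HFE and
#'   LFE.
#' @param selection_by_group named list of `c(n_above, n_below)` pairs
#'   per group (default: none injected).
#' @param depth_mean expected reads per sample.
#' @param abundance_shape lognormal sigma of the metacommunity.
#' @param seed integer master seed.
#' @return list with `counts` (SGBs x all samples), `metadata`,
#'   `taxonomy`, and `truth` (per-slice truth records keyed
#'   "GROUP.TIMEPOINT").
#' @export
simulate_study <- function(n_animals_per_cell = 10,
                           timepoints = TIMEPOINT_LEVELS,
                           n_sgb = 2000,
                           Nm_by_group = c(HFE = 1e4, LFE = 1e4),
                           selection_by_group = NULL,
                           depth_mean = 1e5,
                           abundance_shape = 2,
                           seed = 1L) {
  groups <- FE_LEVELS
  if (!all(groups %in% names(Nm_by_group)))
    stop("Nm_by_group must name both HFE and LFE", call. = FALSE)
  timepoints <- normalize_timepoint(timepoints)
  if (length(timepoints) < 1L) stop("need >= 1 timepoint", call. = FALSE)
  sgb_ids <- sprintf("SGB%04d", seq_len(n_sgb))

  p_meta <- withr::with_seed(seed, {
    raw <- stats::rlnorm(n_sgb, 0, abundance_shape)
    raw / sum(raw)
  })

  animal_ids <- list(
    HFE = sprintf("H%02d", seq_len(n_animals_per_cell)),
    LFE = sprintf("L%02d", seq_len(n_animals_per_cell)))
  # diets split within each efficiency group, constant per animal
  diets <- lapply(animal_ids, function(a)
    rep(c("F", "G"), length.out = length(a)))

  # selection targets are drawn once per group so that the same taxa
  # stay under selection across all timepoints (persistent lineages)
  targets <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    sel <- selection_by_group[[g]]
    if (is.null(sel) || (sel[[1]] == 0 && sel[[2]] == 0)) next
    targets[[g]] <- withr::with_seed(
      as.integer((as.double(seed) * 613 + gi * 97) %% 2147483629), {
        terc <- cut(rank(p_meta, ties.method = "first"), breaks = 3,
                    labels = c("low", "mid", "high"))
        lo <- which(terc == "low")
        # below-taxa capped in metacommunity abundance so that zeroing
        # them moves no column total by even ~0.5%
        mid <- which(terc == "mid" & p_meta < 0.002 / max(1, sel[[2]]))
        if (length(lo) < sel[[1]] || length(mid) < sel[[2]])
          stop("not enough eligible SGBs for the requested selection",
               call. = FALSE)
        ab <- if (sel[[1]] > 0) sample(lo, sel[[1]]) else integer()
        be <- if (sel[[2]] > 0) sample(setdiff(mid, ab), sel[[2]])
              else integer()
        list(above = sgb_ids[ab], below = sgb_ids[be])
      })
  }

  blocks <- list(); meta <- list(); truths <- list()
  slice_idx <- 0L
  for (g in groups) {
    for (tp in timepoints) {
      slice_idx <- slice_idx + 1L
      sub_seed <- as.integer((as.double(seed) * 1009 +
                                slice_idx * 7919) %% 2147483629)
      ids <- paste(animal_ids[[g]], tp, sep = "_")
      sim <- simulate_neutral_slice(
        n_sgb, n_animals_per_cell, Nm_true = Nm_by_group[[g]],
        depth_mean = depth_mean, abundance_shape = abundance_shape,
        seed = sub_seed, sgb_ids = sgb_ids, sample_ids = ids,
        p_meta = p_meta)
      if (!is.null(targets[[g]])) {
        sim <- inject_selection(sim$counts, sim$truth,
                                n_above = 0, n_below = 0,
                                seed = sub_seed + 1L,
                                above_ids = targets[[g]]$above,
                                below_ids = targets[[g]]$below)
      }
      blocks[[paste(g, tp, sep = ".")]] <- sim$counts
      truths[[paste(g, tp, sep = ".")]] <- sim$truth
      meta[[paste(g, tp, sep = ".")]] <- data.frame(
        sample_id = ids, animal_id = animal_ids[[g]],
        diet = diets[[g]], fe_group = g, timepoint = tp,
        stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, unname(blocks))
  metadata <- do.call(rbind, unname(meta))
  rownames(metadata) <- NULL

  # Genus labels: injected above-taxa (union over slices) concentrate in
  # g__TestPos, below-taxa in g__TestNeg, remainder spread over
  # background genera.
  sel_above <- unique(unlist(lapply(truths, `[[`, "selected_above")))
  sel_below <- unique(unlist(lapply(truths, `[[`, "selected_below")))
  genus <- withr::with_seed(seed + 2L, {
    bg <- sprintf("Bg%02d", 1:20)
    g <- sample(bg, n_sgb, replace = TRUE)
    names(g) <- sgb_ids
    g[sel_above] <- "TestPos"
    g[setdiff(sel_below, sel_above)] <- "TestNeg"
    g
  })
  taxonomy <- data.frame(
    sgb_id = sgb_ids,
    lineage = sprintf(
      "d__Bacteria;p__SimPhylum;c__SimClass;o__SimOrder;f__SimFamily;g__%s;s__%s sp%s",
      genus, genus, seq_len(n_sgb)),
    stringsAsFactors = FALSE)
  taxonomy <- validate_taxonomy(taxonomy)

  list(counts = counts, metadata = validate_sample_metadata(metadata),
       taxonomy = taxonomy, truth = truths)
}

#' Simulate a dbCAN-style domain-architecture table
#'
#' Draws random multi-domain architectures from CAZyme-like token pools
#' (CBMx, GHx, GHx_y, PLx, CEx, AAx, plus non-CAZy tokens).  A designated
#' fraction of genomes is "CBM-rich": their proteins have an elevated
#' probability of carrying a tandem CBM run of length 2-3 adjacent to a
#' GH domain, mimicking tandem-CBM catalytic architectures.
#'
#' @param n_genomes number of genomes (>= 1).
#' @param n_proteins_per_genome proteins per genome (>= 1).
#' @param cbm_rich_fraction fraction of genomes flagged CBM-rich.
#' @param seed integer seed.
#' @return data frame with columns `protein_id`, `genome_id`,
#'   `architecture`, plus a `rich_genomes` attribute naming the flagged
#'   genomes.
#' @export
simulate_domain_annotations <- function(n_genomes, n_proteins_per_genome,
                                        cbm_rich_fraction = 0.5,
                                        seed = 1L) {
  if (n_genomes < 1 || n_proteins_per_genome < 1)
    stop("counts must be >= 1", call. = FALSE)
  if (cbm_rich_fraction < 0 || cbm_rich_fraction > 1)
    stop("cbm_rich_fraction must lie in [0, 1]", call. = FALSE)
  cbm_pool <- paste0("CBM", c(2, 3, 6, 9, 11, 13, 26, 32, 86, 91))
  gh_pool <- c(paste0("GH", c(5, 10, 13, 29, 51)),
               paste0("GH43_", c(10, 16, 29)))
  cat_pool <- c(gh_pool, "PL1", "PL11", "CE1", "CE6", "AA3")
  other_pool <- c("SLH", "DOC", "FN3", "UNK")
  pool <- c(cbm_pool, cat_pool, other_pool)

  withr::with_seed(seed, {
    n_rich <- round(cbm_rich_fraction * n_genomes)
    genome_ids <- sprintf("G%03d", seq_len(n_genomes))
    rich <- if (n_rich > 0) sample(genome_ids, n_rich) else character()
    rows <- vector("list", n_genomes)
    for (gi in seq_len(n_genomes)) {
      gid <- genome_ids[gi]
      is_rich <- gid %in% rich
      archs <- character(n_proteins_per_genome)
      for (pi in seq_len(n_proteins_per_genome)) {
        if (is_rich && stats::runif(1) < 0.30) {
          run <- sample(2:3, 1L)
          cbm <- sample(cbm_pool, 1L)
          toks <- c(rep(cbm, run), sample(gh_pool, 1L))
          if (stats::runif(1) < 0.5) toks <- rev(toks)
        } else {
          k <- sample(1:4, 1L, prob = c(0.4, 0.3, 0.2, 0.1))
          toks <- sample(pool, k, replace = TRUE)
        }
        archs[pi] <- paste(toks, collapse = "+")
      }
      rows[[gi]] <- data.frame(
        protein_id = sprintf("%s_p%04d", gid,
                             seq_len(n_proteins_per_genome)),
        genome_id = gid, architecture = archs,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "rich_genomes") <- rich
    out
  })
}
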