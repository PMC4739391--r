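#' Configuration for a simulated congeneric barcode dataset
#'
#' Describes a genus-level simulation: a star-like species tree whose
#' between-species paths average `target_inter` and whose within-species
#' depths average `target_intra` (both in expected substitutions/site),
#' sequences evolved from a root of composition `gc_target` under a
#' two-rate (transition/transversion) substitution process with rate
#' ratio `kappa`, Poisson indel events with geometric lengths, and
#' optional planted species-diagnostic features.
#'
#' @param n_species number of species.
#' @param accessions_per_species accessions per species; a single count
#'   or a vector of length `n_species`.
#' @param root_length root sequence length in bp.
#' @param kappa transition/transversion rate ratio (> 0).
#' @param target_intra expected conspecific pairwise distance.
#' @param target_inter expected heterospecific pairwise distance; must
#'   exceed `target_intra`.
#' @param gc_target root GC fraction in (0, 1).
#' @param indel_rate indel events per site per unit branch length.
#' @param planted_features list of feature specifications; each a list
#'   with `species` (species index), `kind` ("homopolymer",
#'   "tandem_repeat" or "inversion") and kind-specific fields: `base` +
#'   `len` for homopolymers, `unit` + `copies` for tandem repeats,
#'   `len` for inversions.
#' @param seed integer seed controlling every random draw.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_species = 10, accessions_per_species = 5,
                              root_length = 500, kappa = 2,
                              target_intra = 0.006, target_inter = 0.035,
                              gc_target = 0.5, indel_rate = 0.02,
                              planted_features = list(), seed = 1) {
  stopifnot(target_inter > target_intra, target_intra >= 0,
            gc_target > 0, gc_target < 1, kappa > 0, n_species >= 2)
  if (length(accessions_per_species) == 1L)
    accessions_per_species <- rep(accessions_per_species, n_species)
  stopifnot(length(accessions_per_species) == n_species)
  structure(list(n_species = n_species,
                 accessions_per_species = accessions_per_species,
                 root_length = root_length, kappa = kappa,
                 target_intra = target_intra,
                 target_inter = target_inter,
                 gc_target = gc_target, indel_rate = indel_rate,
                 planted_features = planted_features, seed = seed),
            class = "simulation_config")
}

#' Named simulation presets
#'
#' Two contrasting locus regimes: `"ITS2"` mirrors a short, GC-rich,
#' moderately divergent nuclear spacer (intra 0.006, inter 0.035, GC
#' 0.66, 220 bp); `"psbA-trnH"` mirrors a short, AT-rich, highly
#' divergent chloroplast spacer (intra 0.048, inter 0.107, GC 0.25,
#' 287 bp).
#'
#' @param preset preset name.
#' @param ... overrides passed to [simulation_config()].
#' @return a `simulation_config`.
#' @export
sim_preset <- function(preset = c("ITS2", "psbA-trnH"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    "ITS2" = list(target_intra = 0.006, target_inter = 0.035,
                  gc_target = 0.66, root_length = 220),
    "psbA-trnH" = list(target_intra = 0.048, target_inter = 0.107,
                       gc_target = 0.25, root_length = 287))
  args <- utils::modifyList(base, list(...))
  do.call(simulation_config, args)
}

.sim_species_name <- function(i) sprintf("Simulata taxon%02d", i)
.sim_tip_label <- function(sp, acc) sprintf("T%02d_%d", sp, acc)

#' Simulate a species tree with accession tips
#'
#' Builds a star-like genus tree: species stems radiate from the root
#' with length about `target_inter / 2` (small lognormal jitter), and
#' each species' accessions hang star-like from the species ancestor at
#' depth about `target_intra / 2`, so conspecific path lengths average
#' `target_intra` and heterospecific paths `target_inter`.
#' Deterministic given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return an ape `phylo` tree with `attr(tree, "species")` mapping tip
#'   labels to species names.
#' @export
simulate_species_tree <- function(config) {
  .with_seed(config$seed, {
    # tip-to-tip heterospecific paths are stem_i + stem_j + depth_i +
    # depth_j, so the accession depth is subtracted from the stems to
    # keep the expected path at target_inter
    half_intra <- config$target_intra / 2
    half_inter <- (config$target_inter - config$target_intra) / 2
    sp_parts <- character(config$n_species)
    species_map <- character(0)
    for (s in seq_len(config$n_species)) {
      n_acc <- config$accessions_per_species[s]
      # lognormal jitter with mean 1 so expectations hit the targets
      stem <- half_inter * exp(rnorm(1, -0.08^2 / 2, 0.08))
      tips <- vapply(seq_len(n_acc), function(a) .sim_tip_label(s, a), "")
      species_map <- c(species_map,
                       stats::setNames(rep(.sim_species_name(s), n_acc),
                                       tips))
      if (n_acc == 1L) {
        sp_parts[s] <- sprintf("%s:%.10f", tips, stem + half_intra)
      } else {
        depth <- half_intra * exp(rnorm(n_acc, -0.15^2 / 2, 0.15))
        if (config$target_intra == 0) depth <- rep(0, n_acc)
        sp_parts[s] <- sprintf("(%s):%.10f",
                               paste(sprintf("%s:%.10f", tips, depth),
                                     collapse = ","),
                               stem)
      }
    }
    txt <- paste0("(", paste(sp_parts, collapse = ","), ");")
    tr <- ape::read.tree(text = txt)
    attr(tr, "species") <- species_map
    tr
  })
}

.ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
.tv_partners <- list(A = c("C", "T"), G = c("C", "T"),
                     C = c("A", "G"), T = c("A", "G"))

# evolve one sequence (character vector) along a branch of length t
.evolve_branch <- function(ch, t, kappa, indel_rate, gc) {
  L <- length(ch)
  if (t > 0 && L > 0) {
    n_sub <- rpois(1, t * L)
    if (n_sub > 0) {
      sites <- sample.int(L, n_sub, replace = TRUE)
      p_ts <- kappa / (kappa + 2)
      for (s in sites) {
        b <- ch[s]
        if (!b %in% c("A", "C", "G", "T")) next
        ch[s] <- if (runif(1) < p_ts) .ts_partner[[b]]
                 else sample(.tv_partners[[b]], 1)
      }
    }
    n_indel <- rpois(1, indel_rate * t * L)
    for (k in seq_len(n_indel)) {
      len <- 1L + rgeom(1, 1 / 3)   # geometric lengths, mean 3
      L <- length(ch)
      if (runif(1) < 0.5 && L > len + 10) {  # deletion
        at <- sample.int(L - len, 1)
        ch <- ch[-(at:(at + len - 1L))]
      } else {                               # insertion
        at <- sample.int(L, 1)
        ins <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                      prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
        ch <- append(ch, ins, after = at)
      }
    }
  }
  ch
}

#' Evolve sequences along a tree
#'
#' Draws a root sequence with the configured GC composition, then
#' applies substitutions along each branch as Poisson events (rate =
#' branch length x sites) placed uniformly over sites, with transition
#' probability kappa/(kappa + 2) per event, plus Poisson indel events
#' with geometric lengths (mean 3). Branch lengths are in expected
#' substitutions/site, matching the K2P distance scale. Deterministic
#' given `config$seed`.
#'
#' @param tree an ape `phylo` with tip labels and (optionally) a
#'   species attribute, e.g. from [simulate_species_tree()].
#' @param config a [simulation_config()].
#' @return a [locus_dataset()] with one record per tip.
#' @export
evolve_sequences <- function(tree, config) {
  .with_seed(config$seed + 1L, {
    gc <- config$gc_target
    root_seq <- sample(c("A", "C", "G", "T"), config$root_length,
                       replace = TRUE,
                       prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    n_tip <- length(tree$tip.label)
    n_node <- n_tip + tree$Nnode
    seqs <- vector("list", n_node)
    root <- n_tip + 1L
    seqs[[root]] <- root_seq
    # process edges only once their parent sequence exists (preorder)
    edges <- tree$edge
    pending <- seq_len(nrow(edges))
    while (length(pending)) {
      ready <- pending[!vapply(edges[pending, 1],
                               function(p) is.null(seqs[[p]]), logical(1))]
      for (e in ready) {
        seqs[[edges[e, 2]]] <- .evolve_branch(
          seqs[[edges[e, 1]]], tree$edge.length[e], config$kappa,
          config$indel_rate, gc)
      }
      pending <- setdiff(pending, ready)
    }
    species_map <- attr(tree, "species")
    ids <- tree$tip.label
    records <- data.frame(
      accession_id = ids,
      species = if (!is.null(species_map)) unname(species_map[ids])
                else "Simulata taxon01",
      sequence = vapply(seqs[seq_len(n_tip)], paste, "", collapse = ""),
      stringsAsFactors = FALSE)
    locus_dataset(records, locus = "simulated",
                  provenance = sprintf("simulated (seed %d)", config$seed))
  })
}

# ---- feature planting -------------------------------------------------

# normalize a feature spec, filling kind-specific defaults
.feature_spec <- function(spec) {
  if (spec$kind == "homopolymer") {
    list(kind = "homopolymer",
         base = if (is.null(spec$base)) "A" else spec$base,
         len = if (is.null(spec$len)) 7L else as.integer(spec$len))
  } else if (spec$kind == "tandem_repeat") {
    list(kind = "tandem_repeat",
         unit = if (is.null(spec$unit)) "ATTAAA" else spec$unit,
         copies = if (is.null(spec$copies)) 2L else as.integer(spec$copies))
  } else if (spec$kind == "inversion") {
    list(kind = "inversion",
         len = if (is.null(spec$len)) 74L else as.integer(spec$len))
  } else stop("unknown feature kind: ", spec$kind)
}

# Plant one species' features into every carrier sequence at a shared
# coordinate (a feature models a single evolutionary event, so it is
# homologous across the species). Every feature must be recoverable at
# its exact coordinates on every final sequence; placements that
# interfere with each other or with the local sequence context are
# resampled. Insertions are applied first (an insertion left of an
# earlier plant shifts its recorded coordinates), the inversion last,
# with each carrier's pre-inversion sequence kept as its detection
# reference.
.plant_all <- function(seqs, specs, max_tries = 100) {
  specs <- lapply(specs, .feature_spec)
  is_inv <- vapply(specs, function(s) s$kind == "inversion", logical(1))
  specs <- c(specs[!is_inv], specs[is_inv])  # inversions applied last
  for (attempt in seq_len(max_tries)) {
    cur <- seqs
    intervals <- matrix(numeric(0), ncol = 2)
    truth <- list()
    references <- NULL
    ok <- TRUE
    for (spec in specs) {
      L <- min(nchar(cur))
      if (spec$kind == "inversion") {
        len <- spec$len
        if (len + 20 > L) stop("inversion longer than sequence")
        slots <- setdiff(seq(10L, L - len - 10L),
                         unlist(apply(intervals, 1, function(iv)
                           seq(iv[1] - len - 2L, iv[2] + 2L))))
        if (!length(slots)) { ok <- FALSE; break }
        s <- if (length(slots) == 1L) slots else sample(slots, 1)
        e <- s + len - 1L
        references <- cur
        cur <- vapply(cur, function(x)
          paste0(substr(x, 1, s - 1), revcomp(substr(x, s, e)),
                 substr(x, e + 1, nchar(x))), "", USE.NAMES = FALSE)
        truth[[length(truth) + 1L]] <- list(kind = "inversion",
                                            start = s, end = e,
                                            motif = "", copies = 1L)
        intervals <- rbind(intervals, c(s, e))
      } else {
        insert <- if (spec$kind == "homopolymer")
          strrep(spec$base, spec$len) else strrep(spec$unit, spec$copies)
        l <- nchar(insert)
        # insertion goes after position p; keep clear of existing plants
        slots <- setdiff(seq(10L, L - 10L),
                         unlist(apply(intervals, 1, function(iv)
                           seq(iv[1] - 3L - l, iv[2] + 3L))))
        if (!length(slots)) { ok <- FALSE; break }
        p <- if (length(slots) == 1L) slots else sample(slots, 1)
        cur <- vapply(cur, function(x)
          paste0(substr(x, 1, p), insert, substr(x, p + 1, nchar(x))),
          "", USE.NAMES = FALSE)
        # shift previously planted intervals lying right of the insertion
        shift <- intervals[, 1] > p
        intervals[shift, ] <- intervals[shift, , drop = FALSE] + l
        for (k in seq_along(truth)) {
          if (truth[[k]]$start > p) {
            truth[[k]]$start <- truth[[k]]$start + l
            truth[[k]]$end <- truth[[k]]$end + l
          }
        }
        truth[[length(truth) + 1L]] <- list(
          kind = spec$kind, start = p + 1L, end = p + l,
          motif = if (spec$kind == "homopolymer") spec$base else spec$unit,
          copies = if (spec$kind == "homopolymer") spec$len else spec$copies)
        intervals <- rbind(intervals, c(p + 1L, p + l))
      }
    }
    if (!ok) next
    all_ok <- all(vapply(seq_along(cur), function(i)
      .verify_planted(cur[i], truth,
                      if (is.null(references)) NULL else references[i]),
      logical(1)))
    if (all_ok)
      return(list(seqs = cur, truth = truth, references = references))
  }
  stop("could not place planted features without interference")
}

# every planted feature must be recovered at exact coordinates on the
# final sequence by the same detectors users will run
.verify_planted <- function(seq, truth, reference) {
  for (tr in truth) {
    hit <- switch(tr$kind,
      homopolymer = {
        h <- find_homopolymers(seq, min_len = tr$copies)
        any(h$start == tr$start & h$end == tr$end & h$motif == tr$motif)
      },
      tandem_repeat = {
        h <- find_tandem_repeats(
          seq, min_total = nchar(tr$motif) * tr$copies)
        any(h$start == tr$start & h$end == tr$end & h$motif == tr$motif)
      },
      inversion = {
        h <- detect_inversion(seq, reference,
                              min_len = min(50L, tr$end - tr$start + 1L))
        any(h$start == tr$start & h$end == tr$end)
      })
    if (!hit) return(FALSE)
  }
  TRUE
}

#' Simulate a full congeneric dataset with truth
#'
#' Runs [simulate_species_tree()] and [evolve_sequences()], then plants
#' the configured diagnostic features into every accession of their
#' target species, at one shared coordinate per feature (a feature
#' models a single evolutionary event, homologous across the species).
#' Positions are drawn at random but rejection-checked so that each
#' planted feature is maximal and detectable at its exact coordinates
#' in every carrier (e.g. a planted poly-A run is not extended by a
#' neighboring A). For inversions the pre-inversion sequence of each
#' carrier is retained as the detection reference.
#'
#' @param config a [simulation_config()].
#' @return a `simulated_dataset`: list with `dataset` (a
#'   [locus_dataset()]), `truth_tree`, `truth_features` (a
#'   `feature_hits` data frame), `references` (named character vector of
#'   pre-inversion sequences) and `config`.
#' @export
simulate_dataset <- function(config) {
  tree <- simulate_species_tree(config)
  dataset <- evolve_sequences(tree, config)
  truth <- list()
  references <- character(0)
  if (length(config$planted_features)) {
    .with_seed(config$seed + 2L, {
      rec <- dataset$records
      sp_idx <- vapply(config$planted_features, function(s) s$species, 0)
      for (sp in unique(sp_idx)) {
        sp_name <- .sim_species_name(sp)
        carriers <- which(rec$species == sp_name)
        if (!length(carriers))
          stop("no accessions for planted species index ", sp)
        specs <- config$planted_features[sp_idx == sp]
        planted <- .plant_all(rec$sequence[carriers], specs)
        rec$sequence[carriers] <- planted$seqs
        if (!is.null(planted$references))
          references[rec$accession_id[carriers]] <- planted$references
        for (i in carriers) {
          for (tr in planted$truth) {
            truth[[length(truth) + 1L]] <- data.frame(
              kind = tr$kind, sequence_id = rec$accession_id[i],
              start = tr$start, end = tr$end,
              length = tr$end - tr$start + 1L,
              motif = tr$motif, copies = tr$copies, identity = 1,
              stringsAsFactors = FALSE)
          }
        }
      }
      dataset$records <- rec
    })
  }
  truth_features <- if (length(truth)) {
    structure(do.call(rbind, truth),
              class = c("feature_hits", "data.frame"))
  } else {
    .feature_hits(character(0), character(0), integer(0), integer(0),
                  character(0), integer(0), numeric(0))
  }
  structure(list(dataset = dataset, truth_tree = tree,
                 truth_features = truth_features,
                 references = references, config = config),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("<simulated_dataset>", n_records(x$dataset), "accessions,",
      x$config$n_species, "species,",
      nrow(x$truth_features), "planted feature(s)\n")
  invisible(x)
}

#' Analytic expectations for a simulated dataset
#'
#' Reports what the generating process implies: expected pooled intra-
#' and interspecific distances (the configured targets) and, when the
#' inter/intra gap ratio is at least 5, an expected species-level
#' identification efficiency of 100 percent. For smaller ratios the
#' efficiency is not predicted (NA).
#'
#' @param sim a `simulated_dataset` from [simulate_dataset()], or a
#'   [simulation_config()].
#' @return a list with `expected_all_intra`, `expected_all_inter`,
#'   `gap_ratio`, `expected_efficiency` (percent or NA) and
#'   `efficiency_predicted`.
#' @export
truth_report <- function(sim) {
  config <- if (inherits(sim, "simulated_dataset")) sim$config else sim
  ratio <- if (config$target_intra > 0)
    config$target_inter / config$target_intra else Inf
  predicted <- ratio >= 5
  list(expected_all_intra = config$target_intra,
       expected_all_inter = config$target_inter,
       gap_ratio = ratio,
       expected_efficiency = if (predicted) 100 else NA_real_,
       efficiency_predicted = predicted)
}
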