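# Seeded generators for every input the pipeline consumes, with planted
# ground truth for parameter-recovery testing. A single study seed is
# expanded into per-generator substreams (fixed offsets), so adding one
# generator to a workflow never perturbs the draws of another.

#' Simulation configuration
#'
#' Collects every knob of the synthetic study in one validated list. The
#' defaults define the study conditions exercised throughout the test
#' suite: a 10-condition developmental time course of 2,000 paralog pairs
#' with 35% planted divergence, 60 complexes of 5-12 members with paralog-
#' coupled dispersion, and a 4-species proteome panel with 7 comparisons,
#' 3 replicates and 50 of 1,000 orthogroup pairs carrying a planted
#' log2-ratio shift of 1.
#'
#' @param n_pairs Number of paralog pairs.
#' @param n_singletons Genes without paralogs.
#' @param n_conditions Conditions (time points) in the expression study.
#' @param n_replicates Replicates per condition (expression study).
#' @param divergent_fraction Planted fraction of divergent pairs in \[0,1\].
#' @param noise_sd Per-sample noise sd in log2 units, relative to the
#'   unit-sd latent profiles.
#' @param complex_sizes Member counts of the simulated complexes.
#' @param content_coupling Strength linking paralog content to complex
#'   member dispersion (0 = none; members with paralogs get noise sd
#'   scaled by `1 + content_coupling`).
#' @param paralog_var_boost Amplitude multiplier for paralog-gene profiles
#'   (drives the higher CV of paralog genes; 1 disables).
#' @param protein_noise_sd Extra independent noise of the protein layer.
#' @param ned_prob_complex,ned_prob_other Probability that a complex-member
#'   / other gene is labelled NED (non-exponentially degraded).
#' @param ned_extra_noise Extra protein-layer noise sd for pairs containing
#'   a NED member (lowers their protein co-expression, hence their delta).
#' @param n_species Species in the multispecies panel.
#' @param n_comparisons Total condition comparisons across species
#'   (default 7).
#' @param n_og_pairs Orthogroup pairs in the panel.
#' @param n_conserved Planted conserved pairs.
#' @param effect_size Planted log2-ratio shift of conserved pairs.
#' @param ms_noise_sd Replicate noise sd of the panel (log2 units).
#' @param ms_replicates Replicates per condition in the panel.
#' @param seed Integer study seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_pairs = 2000, n_singletons = 500,
                              n_conditions = 10, n_replicates = 1,
                              divergent_fraction = 0.35, noise_sd = 0.3,
                              complex_sizes = rep(c(5, 6, 7, 8, 10, 12), 10),
                              content_coupling = 1,
                              paralog_var_boost = 1.5,
                              protein_noise_sd = 0.3,
                              ned_prob_complex = 0.45,
                              ned_prob_other = 0.2,
                              ned_extra_noise = 0.5,
                              n_species = 4, n_comparisons = 7,
                              n_og_pairs = 1000, n_conserved = 50,
                              effect_size = 1, ms_noise_sd = 0.25,
                              ms_replicates = 3, seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("n_pairs", "n_singletons", "n_conditions", "n_replicates",
              "n_species", "n_comparisons", "n_og_pairs", "n_conserved",
              "ms_replicates")
  for (nm in counts) {
    if (cfg[[nm]] < 0) abort(paste0("`", nm, "` must be >= 0."))
  }
  if (cfg$divergent_fraction < 0 || cfg$divergent_fraction > 1) {
    abort("`divergent_fraction` must lie in [0, 1].")
  }
  if (cfg$noise_sd < 0) abort("`noise_sd` must be non-negative.")
  structure(cfg, class = "simulation_config")
}

# standardized latent trajectory: a random walk over conditions scaled to
# mean 0, sd 1, so noise_sd is directly "fraction of latent sd"
latent_profile <- function(n_conditions) {
  l <- cumsum(rnorm(n_conditions))
  s <- sd(l)
  if (is.na(s) || s == 0) return(rep(0, n_conditions))
  (l - mean(l)) / s
}

#' Simulate a paired expression study with planted divergence and complexes
#'
#' Generates an RNA and a protein expression dataset over a developmental-
#' style time course, a canonical paralog pair table, a complex catalog,
#' and the planted ground truth. Each pair shares a smooth latent
#' trajectory; co-regulated pairs follow it with independent noise,
#' divergent pairs use the latent with opposite signs, so the divergence
#' classifier should recover the planted fraction. Complexes are built
#' around their own latent trajectories from co-regulated pairs and
#' singleton genes, with a per-complex target paralog content; when
#' `content_coupling > 0`, members that have paralogs receive inflated
#' noise, coupling paralog content to complex variability.
#'
#' @param cfg A [simulation_config()].
#' @return A list: `rna` and `protein` ([expression_dataset()]s, log2
#'   scale), `pairs` (canonical pair tibble), `catalog` (named list),
#'   `truth` (list with `pairs`, `genes`, `complexes` tibbles).
#' @export
simulate_expression_study <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  withr::local_seed(cfg$seed)
  n_genes_total <- 2 * cfg$n_pairs + cfg$n_singletons
  if (length(cfg$complex_sizes) &&
      max(cfg$complex_sizes) > n_genes_total) {
    abort("A complex is larger than the total gene count.")
  }
  pair_idx <- seq_len(cfg$n_pairs)
  genes_a <- sprintf("gp%04da", pair_idx)
  genes_b <- sprintf("gp%04db", pair_idx)
  singletons <- sprintf("gs%04d", seq_len(cfg$n_singletons))

  mean_ident <- runif(cfg$n_pairs, 20, 95)
  half_gap <- runif(cfg$n_pairs, 0, 5)
  pairs <- tibble(
    gene_a = genes_a, gene_b = genes_b,
    identity_ab = pmin(100, mean_ident + half_gap),
    identity_ba = pmax(0, mean_ident - half_gap)
  ) %>% canonicalize_pairs()

  divergent <- rep(FALSE, cfg$n_pairs)
  n_div <- round(cfg$n_pairs * cfg$divergent_fraction)
  if (n_div > 0) divergent[sample.int(cfg$n_pairs, n_div)] <- TRUE

  # --- complex assembly: co-regulated pairs + singletons, target content
  catalog <- list()
  complex_truth <- NULL
  pair_complex <- rep(NA_integer_, cfg$n_pairs)   # first complex of a pair
  singleton_complex <- rep(NA_integer_, cfg$n_singletons)
  free_pairs <- which(!divergent)
  free_singles <- seq_len(cfg$n_singletons)
  if (length(cfg$complex_sizes)) {
    target_content <- runif(length(cfg$complex_sizes), 0.1, 0.9)
    for (ci in seq_along(cfg$complex_sizes)) {
      size <- cfg$complex_sizes[ci]
      n_par <- round(target_content[ci] * size)
      n_full <- n_par %/% 2
      members <- character(0)
      used_pairs <- integer(0)
      take <- function(pool, n) {
        if (length(pool) >= n) pool[seq_len(n)] else pool
      }
      sel <- take(free_pairs, n_full)
      free_pairs <- setdiff(free_pairs, sel)
      used_pairs <- c(used_pairs, sel)
      members <- c(members, genes_a[sel], genes_b[sel])
      if (n_par %% 2 == 1) {          # odd slot: one gene of a fresh pair
        sel1 <- take(free_pairs, 1)
        free_pairs <- setdiff(free_pairs, sel1)
        used_pairs <- c(used_pairs, sel1)
        members <- c(members, genes_a[sel1])
      }
      n_single <- size - length(members)
      if (n_single > 0) {
        ssel <- take(free_singles, n_single)
        free_singles <- setdiff(free_singles, ssel)
        members <- c(members, singletons[ssel])
        singleton_complex[ssel] <- ci
      }
      pair_complex[used_pairs] <- ci
      id <- sprintf("cpx%03d", ci)
      catalog[[id]] <- members
      complex_truth <- bind_rows(complex_truth, tibble(
        complex_id = id, size = length(members),
        target_content = target_content[ci]
      ))
    }
  }

  # --- latent trajectories
  complex_latents <- replicate(length(catalog),
                               latent_profile(cfg$n_conditions))
  pair_latents <- vapply(pair_idx, function(i) {
    if (!is.na(pair_complex[i])) complex_latents[, pair_complex[i]]
    else latent_profile(cfg$n_conditions)
  }, numeric(cfg$n_conditions))
  single_latents <- vapply(seq_len(cfg$n_singletons), function(i) {
    if (!is.na(singleton_complex[i])) complex_latents[, singleton_complex[i]]
    else latent_profile(cfg$n_conditions)
  }, numeric(max(cfg$n_conditions, 1)))

  all_genes <- c(genes_a, genes_b, singletons)
  in_complex <- all_genes %in% unlist(catalog, use.names = FALSE)
  names(in_complex) <- all_genes
  has_par <- c(rep(TRUE, 2 * cfg$n_pairs), rep(FALSE, cfg$n_singletons))
  names(has_par) <- all_genes

  noise_sd_of <- function(g) {
    s <- cfg$noise_sd
    if (in_complex[g] && has_par[g]) s * (1 + cfg$content_coupling) else s
  }

  conds <- sprintf("t%02d", seq_len(cfg$n_conditions))
  reps <- sprintf("r%d", seq_len(cfg$n_replicates))
  grid <- expand.grid(replicate = reps, condition = conds,
                      stringsAsFactors = FALSE)[, 2:1]
  samples <- paste(grid$condition, grid$replicate, sep = "_")
  cond_index <- match(grid$condition, conds)

  profile_of <- function(g) {
    if (g %in% genes_a) {
      i <- match(g, genes_a)
      pair_latents[, i]
    } else if (g %in% genes_b) {
      i <- match(g, genes_b)
      if (divergent[i]) -pair_latents[, i] else pair_latents[, i]
    } else {
      single_latents[, match(g, singletons)]
    }
  }

  base <- runif(length(all_genes), 4, 10)
  names(base) <- all_genes
  rna_values <- t(vapply(all_genes, function(g) {
    prof <- profile_of(g)[cond_index] +
      rnorm(length(samples), 0, noise_sd_of(g))
    if (has_par[g]) prof <- prof * cfg$paralog_var_boost
    base[g] + prof
  }, numeric(length(samples))))
  colnames(rna_values) <- samples

  meta_rna <- tibble(sample = samples, condition = grid$condition,
                     replicate = grid$replicate, layer = "rna",
                     species = "sim")
  rna <- expression_dataset(rna_values, meta_rna, scale = "log2")

  # --- protein layer: rna + independent noise + NED-pair extra noise
  ned_prob <- if_else(in_complex, cfg$ned_prob_complex, cfg$ned_prob_other)
  ned <- runif(length(all_genes)) < ned_prob
  names(ned) <- all_genes
  pair_has_ned <- ned[genes_a] | ned[genes_b]
  extra_sd <- setNames(rep(0, length(all_genes)), all_genes)
  extra_sd[genes_a[pair_has_ned]] <- cfg$ned_extra_noise
  extra_sd[genes_b[pair_has_ned]] <- cfg$ned_extra_noise
  prot_values <- rna_values +
    matrix(rnorm(length(rna_values), 0, cfg$protein_noise_sd),
           nrow(rna_values)) +
    matrix(rnorm(length(rna_values)), nrow(rna_values)) * extra_sd
  meta_prot <- mutate(meta_rna, layer = "protein")
  protein <- expression_dataset(prot_values, meta_prot, scale = "log2")

  truth <- list(
    pairs = tibble(gene_a = genes_a, gene_b = genes_b,
                   divergent = divergent,
                   complex_id = if_else(is.na(pair_complex), NA_character_,
                                        sprintf("cpx%03d", pair_complex)),
                   has_ned = unname(pair_has_ned)),
    genes = tibble(gene = all_genes, has_paralog = unname(has_par),
                   in_complex = unname(in_complex), ned = unname(ned)),
    complexes = if (is.null(complex_truth)) tibble() else complex_truth,
    config = cfg
  )
  list(rna = rna, protein = protein, pairs = pairs, catalog = catalog,
       truth = truth)
}

#' Simulate a multi-species proteome panel with planted conserved pairs
#'
#' Emulates a panel of neuronal-differentiation proteomes from several
#' species, each contributing a share of the canonical condition
#' comparisons (default partition for 4 species: 2+2+2+1 of 7). Each
#' comparison is generated as an independent experimental batch with its
#' own reference replicates, so the non-conserved (null) paralog pairs
#' have ratio changes that are independent across comparisons — the
#' assumption under which Fisher's combined probability is calibrated.
#' Every orthogroup pair is represented by one gene pair per species;
#' planted conserved pairs carry a log2 paralog-ratio shift of
#' `effect_size` (consistent sign across all their comparisons, split half
#' onto each gene), others have no shift. Replicate noise is Gaussian in
#' log2 space.
#'
#' @param cfg A [simulation_config()].
#' @return A list: `datasets` (named list of log2 [expression_dataset()]s,
#'   one per species x comparison batch, named `"<species>.<comparison>"`,
#'   each with conditions `"ref"` and `"cmp<k>"`), `pairs` (named list of
#'   per-species canonical pair tables), `og_map` (orthogroup map tibble),
#'   `species_of` (named vector dataset id -> species), `truth` (tibble:
#'   `og_a`, `og_b`, `conserved`, `sign`, `effect`).
#' @export
simulate_multispecies_proteomes <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (cfg$n_species < 2) abort("Need at least 2 species.")
  if (cfg$n_comparisons < 1) abort("Need at least one comparison.")
  withr::local_seed(cfg$seed + 1L)
  base_share <- cfg$n_comparisons %/% cfg$n_species
  shares <- rep(base_share, cfg$n_species)
  extra <- cfg$n_comparisons - sum(shares)
  if (extra > 0) shares[seq_len(extra)] <- shares[seq_len(extra)] + 1
  species <- sprintf("sp%d", seq_len(cfg$n_species))
  slot_of_species <- split(seq_len(cfg$n_comparisons),
                           rep(seq_len(cfg$n_species), times = shares))

  og_idx <- seq_len(cfg$n_og_pairs)
  og_a <- sprintf("OG%04da", og_idx)
  og_b <- sprintf("OG%04db", og_idx)
  conserved <- rep(FALSE, cfg$n_og_pairs)
  if (cfg$n_conserved > 0 && cfg$effect_size != 0) {
    conserved[sample.int(cfg$n_og_pairs,
                         min(cfg$n_conserved, cfg$n_og_pairs))] <- TRUE
  }
  sgn <- if_else(conserved, sample(c(-1, 1), cfg$n_og_pairs, TRUE), 0)
  truth <- tibble(og_a = og_a, og_b = og_b, conserved = conserved,
                  sign = sgn, effect = sgn * cfg$effect_size)

  datasets <- list()
  pair_tables <- list()
  species_of <- character(0)
  og_map <- NULL
  reps <- sprintf("r%d", seq_len(cfg$ms_replicates))
  for (si in seq_along(species)) {
    sp <- species[si]
    ga <- sprintf("%s.g%04da", sp, og_idx)
    gb <- sprintf("%s.g%04db", sp, og_idx)
    base_a <- rnorm(cfg$n_og_pairs, 20, 2)
    base_b <- rnorm(cfg$n_og_pairs, 20, 2)
    for (slot in slot_of_species[[si]]) {
      cmp <- sprintf("cmp%d", slot)
      grid <- expand.grid(replicate = reps, condition = c("ref", cmp),
                          stringsAsFactors = FALSE)[, 2:1]
      samples <- paste(sp, cmp, grid$condition, grid$replicate, sep = "_")
      shift <- if_else(grid$condition == "ref", 0, 1)
      va <- vapply(seq_along(samples), function(j) {
        base_a + shift[j] * truth$effect / 2 +
          rnorm(cfg$n_og_pairs, 0, cfg$ms_noise_sd)
      }, numeric(cfg$n_og_pairs))
      vb <- vapply(seq_along(samples), function(j) {
        base_b - shift[j] * truth$effect / 2 +
          rnorm(cfg$n_og_pairs, 0, cfg$ms_noise_sd)
      }, numeric(cfg$n_og_pairs))
      values <- rbind(va, vb)
      rownames(values) <- c(ga, gb)
      colnames(values) <- samples
      meta <- tibble(sample = samples, condition = grid$condition,
                     replicate = grid$replicate, layer = "protein",
                     species = sp)
      id <- paste(sp, cmp, sep = ".")
      datasets[[id]] <- expression_dataset(values, meta, scale = "log2")
      species_of[id] <- sp
    }
    pair_tables[[sp]] <- canonicalize_pairs(tibble(
      gene_a = ga, gene_b = gb, identity_ab = 80, identity_ba = 80))
    og_map <- bind_rows(og_map,
                        tibble(gene = c(ga, gb), species = sp,
                               orthogroup = c(og_a, og_b)))
  }
  list(datasets = datasets, pairs = pair_tables, og_map = og_map,
       species_of = species_of, truth = truth)
}

#' Simulate promoter sequences with planted motifs
#'
#' Background sequence is i.i.d. over A/C/G/T with a configurable
#' composition; planted motifs are embedded as their consensus at uniformly
#' random positions (possibly overwriting background, never each other --
#' insertion positions are drawn without overlap when feasible).
#'
#' @param n_genes Number of promoters.
#' @param length Promoter length in bases (default 2000, the upstream
#'   window analyzed).
#' @param motifs List of [motif_model()] objects.
#' @param planted Named list: gene id -> character vector of motif names to
#'   plant. Gene ids default to `prom0001` style; `planted` may reference
#'   any subset.
#' @param composition Background probabilities for A, C, G, T.
#' @param seed Integer seed.
#' @return A list: `promoters` (named character vector) and `truth`
#'   (tibble: `gene`, `tf`, `position`).
#' @export
simulate_promoters <- function(n_genes, length = 2000, motifs = list(),
                               planted = list(),
                               composition = rep(0.25, 4), seed = 1L) {
  widths <- vapply(motifs, function(m) m$width, numeric(1))
  if (base::length(widths) && max(widths) > length) {
    abort("A motif is longer than the promoter.")
  }
  withr::local_seed(seed + 2L)
  genes <- sprintf("prom%04d", seq_len(n_genes))
  proms <- vapply(genes, function(g) {
    paste(sample(c("A", "C", "G", "T"), length, TRUE,
                 prob = composition / sum(composition)), collapse = "")
  }, character(1))
  truth <- NULL
  motif_names <- vapply(motifs, function(m) m$name, character(1))
  for (g in names(planted)) {
    if (!g %in% genes) abort(paste0("Unknown gene in `planted`: ", g))
    occupied <- integer(0)
    for (tf in planted[[g]]) {
      m <- motifs[[match(tf, motif_names)]]
      cons <- motif_consensus(m)
      w <- m$width
      pos_ok <- setdiff(seq_len(length - w + 1),
                        unlist(lapply(occupied, function(o)
                          (o - w + 1):(o + w - 1))))
      pos <- if (base::length(pos_ok)) sample(pos_ok, 1)
             else sample.int(length - w + 1, 1)
      occupied <- c(occupied, pos)
      s <- proms[[g]]
      proms[[g]] <- paste0(substr(s, 1, pos - 1), cons,
                           substr(s, pos + w, length))
      truth <- bind_rows(truth, tibble(gene = g, tf = tf, position = pos))
    }
  }
  list(promoters = proms,
       truth = if (is.null(truth)) tibble(gene = character(),
                                          tf = character(),
                                          position = integer()) else truth)
}

#' Simulate a toy TMT PSM table with planted filtering violations
#'
#' Emits a PSM table in the layout expected by [psm_filter()] /
#' [psm_summarize()]: decoy/contaminant flags, Mascot-style search scores
#' and 10 reporter channels. Violation rates are converted to exact counts
#' (`round(rate * n_psms)`) planted on disjoint PSMs, so the surviving PSM
#' count is known exactly. One extra clean protein with a single unique
#' peptide is appended when `include_single_peptide_protein` is set, to
#' exercise the peptide-count rule.
#'
#' @param n_psms Number of PSMs.
#' @param violation_rates Named list with rates in \[0,1\] for `reverse`,
#'   `contaminant`, `low_score`, `low_intensity`.
#' @param n_proteins Clean proteins sharing the PSMs.
#' @param include_single_peptide_protein Append a clean 1-peptide protein
#'   (its single PSM is part of `n_psms`).
#' @param seed Integer seed.
#' @return A list: `psms` (tibble) and `truth` (list with the planted
#'   counts and `expected_survivors`).
#' @export
simulate_psm_table <- function(n_psms = 20,
                               violation_rates = list(reverse = 0.1,
                                                      contaminant = 0,
                                                      low_score = 0.15,
                                                      low_intensity = 0.05),
                               n_proteins = 4,
                               include_single_peptide_protein = TRUE,
                               seed = 1L) {
  rates <- lapply(violation_rates, function(r) {
    if (r < 0 || r > 1) abort("Violation rates must lie in [0, 1].")
    r
  })
  withr::local_seed(seed + 3L)
  counts <- lapply(rates, function(r) round(r * n_psms))
  n_viol <- sum(unlist(counts))
  if (n_viol > n_psms) abort("Violation rates imply more violations than PSMs.")

  single_idx <- if (include_single_peptide_protein) n_psms else integer(0)
  main_idx <- setdiff(seq_len(n_psms), single_idx)
  protein <- rep(sprintf("P%02d", seq_len(n_proteins)),
                 length.out = length(main_idx))
  # two peptides per protein, enough unique peptides to pass the rule
  peptide <- paste0("pep_", protein, "_",
                    (seq_along(main_idx) %/% n_proteins) %% 3 + 1)
  proteins <- character(n_psms)
  peptides <- character(n_psms)
  proteins[main_idx] <- protein
  peptides[main_idx] <- peptide
  if (length(single_idx)) {
    proteins[single_idx] <- "Psingle"
    peptides[single_idx] <- "pep_single_1"
  }
  intens <- matrix(runif(n_psms * 10, 1e4, 1e6), n_psms, 10)
  colnames(intens) <- paste0("channel_", 1:10)
  score <- runif(n_psms, 20, 60)
  is_reverse <- rep(FALSE, n_psms)
  is_contaminant <- rep(FALSE, n_psms)

  viol_pool <- sample(main_idx)   # violations never hit the 1-peptide PSM
  pos <- 0
  pick <- function(k) {
    out <- viol_pool[pos + seq_len(k)]
    pos <<- pos + k
    out
  }
  is_reverse[pick(counts$reverse)] <- TRUE
  is_contaminant[pick(counts$contaminant)] <- TRUE
  score[pick(counts$low_score)] <- runif(counts$low_score, 2, 14)
  li <- pick(counts$low_intensity)
  intens[li, ] <- runif(length(li) * 10, 10, 900)

  psms <- dplyr::bind_cols(
    tibble(psm_id = sprintf("psm%03d", seq_len(n_psms)),
           protein = proteins, peptide = peptides,
           is_reverse = is_reverse, is_contaminant = is_contaminant,
           score = score),
    as_tibble(intens)
  )
  truth <- list(counts = counts,
                expected_survivors = n_psms - n_viol,
                single_peptide_proteins =
                  if (length(single_idx)) "Psingle" else character(0))
  list(psms = psms, truth = truth)
}
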