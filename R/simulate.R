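#' Configuration for the chemostat multi-omics simulator
#'
#' Defines the study conditions emulated by [simulate_chemostat_dataset()]:
#' a growth-rate (GR) block of carbon-limited NH4 chemostats across a ladder
#' of dilution rates, and a nitrogen-metabolism (NM) block of eight
#' conditions at fixed dilution rate 0.1/h crossing preferred (NH4, Gln,
#' Gln*) and non-preferred (Phe, Ile) nitrogen sources with nitrogen or
#' carbon limitation, in biological triplicate.
#'
#' Gene classes: `growth_dependent` genes follow
#' `m_j * (1 + b_j*mu) / (1 + b_j*mu_ref)` with slopes `b_j` drawn from two
#' lognormal regimes; `ccm_like` genes are flat in `mu` and do not respond
#' to the nitrogen source; `null` genes track growth like the majority but
#' carry no nitrogen response. When `nm_overlap` is `TRUE`,
#' nitrogen-responsiveness overlaps the `growth_dependent` class: those
#' genes are multiplied by `nitrogen_factor` at the mRNA level in
#' preferred-source conditions while their translation rate is divided by
#' the same factor, reproducing the transcription-translation decoupling
#' signature of nitrogen metabolism. Protein abundance is generated exactly
#' as `C_prot = k_sP * C_mRNA / (k_dP + mu)` with `k_sP` proportional to
#' `mu` in the GR block.
#'
#' @param n_genes Number of genes (default 3000).
#' @param replicates Biological replicates per condition (default 3).
#' @param gr_mu GR-block dilution rates, 1/h.
#' @param mu_ref Reference growth rate at which basal abundances are defined.
#' @param class_fractions Named fractions for `growth_dependent`, `ccm_like`,
#'   `null`; must sum to 1.
#' @param nm_overlap Logical; nitrogen-responsiveness overlaps the
#'   growth-dependent class (see Details).
#' @param nitrogen_factor Fold-change applied in preferred-source conditions
#'   (mRNA multiplied, k_sP divided).
#' @param sigma Lognormal measurement noise standard deviation on the
#'   natural-log scale (default 0.2), applied independently per replicate
#'   and layer.
#' @param slope_regimes Centres of the two growth-slope regimes.
#' @param slope_sdlog Lognormal spread of slopes within a regime.
#' @param growth_model `"linear"` (abundance affine in mu) or
#'   `"exponential"` (`exp(b*(mu - mu_ref))`).
#' @param basal_meanlog,basal_sdlog Lognormal parameters of basal mRNA
#'   abundance (mmol/gDW).
#' @param k0_meanlog,k0_sdlog Lognormal parameters of the reference
#'   translation rate (protein/mRNA/h at `mu_ref`).
#' @param kdp_meanlog,kdp_sdlog Lognormal parameters of protein degradation
#'   rates (1/h).
#' @param ribosomal_fraction Fraction of genes flagged ribosomal (drawn from
#'   the high-slope regime).
#' @param n_mrna_spikes,n_protein_spikes Numbers of mRNA and UPS2-like
#'   protein standards.
#' @param spike_power,fpkm_gain,ibaq_gain Signal-generation law:
#'   `signal = gain * amount^power` (lognormal noise `sigma` on top).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(n_genes = 3000L,
                              replicates = 3L,
                              gr_mu = seq(0.05, 0.35, by = 0.05),
                              mu_ref = 0.1,
                              class_fractions = c(growth_dependent = 0.90,
                                                  ccm_like = 0.07,
                                                  null = 0.03),
                              nm_overlap = TRUE,
                              nitrogen_factor = 3,
                              sigma = 0.2,
                              slope_regimes = c(3, 7),
                              slope_sdlog = 0.03,
                              growth_model = c("linear", "exponential"),
                              basal_meanlog = log(1e-9),
                              basal_sdlog = 1.5,
                              k0_meanlog = log(200),
                              k0_sdlog = 0.8,
                              kdp_meanlog = log(0.01),
                              kdp_sdlog = 0.5,
                              ribosomal_fraction = 0.05,
                              n_mrna_spikes = 31L,
                              n_protein_spikes = 48L,
                              spike_power = 1,
                              fpkm_gain = 1e11,
                              ibaq_gain = 1e12,
                              seed = 1L) {
  growth_model <- match.arg(growth_model)
  if (length(unique(gr_mu)) < 2L) {
    stop("GR block needs >= 2 distinct dilution rates", call. = FALSE)
  }
  if (any(gr_mu <= 0) || mu_ref <= 0) {
    stop("growth rates must be > 0", call. = FALSE)
  }
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  req <- c("growth_dependent", "ccm_like", "null")
  if (!all(req %in% names(class_fractions)) ||
      abs(sum(class_fractions[req]) - 1) > 1e-8) {
    stop("class_fractions must be named ", paste(req, collapse = "/"),
         " and sum to 1", call. = FALSE)
  }
  if (nitrogen_factor <= 0) stop("nitrogen_factor must be > 0", call. = FALSE)
  cfg <- list(
    n_genes = as.integer(n_genes), replicates = as.integer(replicates),
    gr_mu = gr_mu, mu_ref = mu_ref,
    class_fractions = class_fractions[req],
    nm_overlap = isTRUE(nm_overlap), nitrogen_factor = nitrogen_factor,
    sigma = sigma, slope_regimes = slope_regimes, slope_sdlog = slope_sdlog,
    growth_model = growth_model,
    basal_meanlog = basal_meanlog, basal_sdlog = basal_sdlog,
    k0_meanlog = k0_meanlog, k0_sdlog = k0_sdlog,
    kdp_meanlog = kdp_meanlog, kdp_sdlog = kdp_sdlog,
    ribosomal_fraction = ribosomal_fraction,
    n_mrna_spikes = as.integer(n_mrna_spikes),
    n_protein_spikes = as.integer(n_protein_spikes),
    spike_power = spike_power, fpkm_gain = fpkm_gain, ibaq_gain = ibaq_gain,
    seed = as.integer(seed)
  )
  class(cfg) <- "SimulationConfig"
  cfg
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# The NM condition grid: 8 conditions at mu = 0.1/h
nm_condition_grid <- function() {
  data.frame(
    limitation = rep(c("nitrogen", "carbon"), each = 4L),
    n_source = c("NH4", "Gln", "Phe", "Ile",
                 "Gln", "Gln*", "Phe", "Ile"),
    stringsAsFactors = FALSE
  )
}

preferred_sources <- function() c("NH4", "Gln", "Gln*", "Glu")

# deterministic largest-remainder apportionment of class counts
class_counts <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  stats::setNames(as.integer(base), names(fractions))
}

# draw per-gene kinetic/regulatory parameters shared by both simulators
draw_gene_params <- function(cfg) {
  n <- cfg$n_genes
  cnt <- class_counts(n, cfg$class_fractions)
  cls <- sample(rep(names(cnt), cnt))
  gene <- sprintf("g%04d", seq_len(n))
  regime <- ifelse(stats::runif(n) < 0.5, 1L, 2L)
  b <- exp(stats::rnorm(n, log(cfg$slope_regimes[regime]), cfg$slope_sdlog))
  b[cls == "ccm_like"] <- 0
  nm_resp <- cfg$nm_overlap & cls == "growth_dependent"
  f <- ifelse(nm_resp, cfg$nitrogen_factor, 1)
  basal <- exp(stats::rnorm(n, cfg$basal_meanlog, cfg$basal_sdlog))
  k0 <- exp(stats::rnorm(n, cfg$k0_meanlog, cfg$k0_sdlog))
  kdp <- exp(stats::rnorm(n, cfg$kdp_meanlog, cfg$kdp_sdlog))
  ribo <- rep(FALSE, n)
  pool <- which(cls == "growth_dependent" & regime == 2L)
  n_ribo <- min(length(pool), round(cfg$ribosomal_fraction * n))
  ribo[sample(pool, n_ribo)] <- TRUE
  data.frame(gene = gene, class = cls, regime = regime, slope = b,
             nm_responsive = nm_resp, nitrogen_factor = f, basal = basal,
             k0 = k0, kdp = kdp, ribosomal = ribo,
             stringsAsFactors = FALSE)
}

growth_term <- function(cfg, b, mu) {
  if (cfg$growth_model == "linear") {
    (1 + b * mu) / (1 + b * cfg$mu_ref)
  } else {
    exp(b * (mu - cfg$mu_ref))
  }
}

#' Simulate a chemostat-style multi-omics dataset with known ground truth
#'
#' Generates the GR + NM condition design, noise-free per-condition truth
#' for mRNA abundance, translation rate and protein abundance (the three
#' satisfy `C_prot = k_sP * C_mRNA / (k_dP + mu)` exactly), then adds
#' multiplicative lognormal noise per replicate and layer and derives the
#' relative-unit measurement layers (FPKM with per-sample depth distortion,
#' iBAQ), spike-in tables, per-sample total RNA/protein contents, and an
#' amino-acid pool table in which Gly and Ser track total transcript output
#' while Gln and Asp stay high and flat.
#'
#' Total protein content per sample is constrained to the 20.6-59.4% of dry
#' weight envelope (and total RNA to 1.8-8.9%) by a single deterministic
#' rescaling of the basal abundance scale; the rescaling preserves the
#' translation-rate identity.
#'
#' @param config A [simulation_config()].
#' @return A `ChemostatSimulation` list with elements `mrna`, `protein`
#'   (absolute `ExpressionMatrix`, mmol/gDW), `mrna_fpkm`, `protein_ibaq`
#'   (relative layers), `design` (`ConditionDesign`), `aa_pools` (condition
#'   x amino acid, umol/gDW), `spikes_mrna`, `spikes_protein`
#'   (`SpikeInTable`), `contents` (`TotalContent`), and `truth`
#'   (`SyntheticTruth`: per-gene parameters, noise-free matrices, spike
#'   law, depth factors, planted cluster number).
#' @export
simulate_chemostat_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  with_seed(config$seed, simulate_chemostat_impl(config))
}

simulate_chemostat_impl <- function(cfg) {
  params <- draw_gene_params(cfg)
  n <- cfg$n_genes

  # --- condition table -----------------------------------------------------
  gr <- data.frame(
    condition = sprintf("GR_mu%.2f", cfg$gr_mu), mu = cfg$gr_mu,
    limitation = "carbon", n_source = "NH4", stringsAsFactors = FALSE)
  nmg <- nm_condition_grid()
  nm <- data.frame(
    condition = sprintf("NM_%s_%s",
                        ifelse(nmg$limitation == "nitrogen", "Nlim", "Clim"),
                        sub("\\*$", "Star", nmg$n_source)),
    mu = cfg$mu_ref, limitation = nmg$limitation, n_source = nmg$n_source,
    stringsAsFactors = FALSE)
  conds <- rbind(gr, nm)
  conds$preferred <- conds$n_source %in% preferred_sources()

  # --- noise-free truth per condition --------------------------------------
  gt <- vapply(conds$mu, function(mu) growth_term(cfg, params$slope, mu),
               numeric(n))
  nf <- outer(params$nitrogen_factor, rep(1, nrow(conds)))
  nf[, !conds$preferred] <- 1
  mrna_true <- params$basal * gt * nf
  ksp_true <- outer(params$k0, conds$mu / cfg$mu_ref) / nf
  prot_true <- ksp_true * mrna_true / outer(params$kdp, conds$mu, `+`)
  dimnames(mrna_true) <- dimnames(ksp_true) <- dimnames(prot_true) <-
    list(params$gene, conds$condition)

  # --- constrain bulk contents to the observed envelopes --------------------
  psum <- colSums(prot_true)
  c_prot <- sqrt(0.206 * 0.594) / sqrt(min(psum) * max(psum))
  # fold the protein rescaling into k0 so the rate identity is preserved
  params$k0 <- params$k0 * c_prot
  ksp_true <- ksp_true * c_prot
  prot_true <- prot_true * c_prot
  rsum <- colSums(mrna_true)
  c_rna <- sqrt(0.018 * 0.089) / sqrt(min(rsum) * max(rsum))

  # --- replicate samples with lognormal noise -------------------------------
  reps <- seq_len(cfg$replicates)
  design <- do.call(rbind, lapply(seq_len(nrow(conds)), function(i) {
    data.frame(sample = sprintf("%s_r%d", conds$condition[i], reps),
               condition = conds$condition[i], mu = conds$mu[i],
               limitation = conds$limitation[i],
               n_source = conds$n_source[i],
               preferred = conds$preferred[i], replicate = reps,
               stringsAsFactors = FALSE)
  }))
  design <- condition_design(design)
  cidx <- match(design$condition, conds$condition)

  noise <- function() {
    if (cfg$sigma == 0) {
      matrix(1, n, nrow(design))
    } else {
      matrix(exp(stats::rnorm(n * nrow(design), 0, cfg$sigma)), n)
    }
  }
  mrna_obs <- mrna_true[, cidx] * noise()
  prot_obs <- prot_true[, cidx] * noise()
  dimnames(mrna_obs) <- dimnames(prot_obs) <- list(params$gene, design$sample)

  # --- relative measurement layers ------------------------------------------
  depth <- exp(stats::rnorm(nrow(design), 0, 0.25))
  depth[1L] <- 1  # reference sample (first GR sample) anchors the scaling
  names(depth) <- design$sample
  fpkm <- cfg$fpkm_gain * sweep(mrna_obs^cfg$spike_power, 2, depth, `*`)
  ibaq <- cfg$ibaq_gain * prot_obs^cfg$spike_power

  contents <- total_content(data.frame(
    sample = design$sample,
    rna_fraction = c_rna * rsum[cidx],
    protein_fraction = colSums(prot_true)[cidx],
    stringsAsFactors = FALSE))

  # --- spike-in tables -------------------------------------------------------
  spike_noise <- function(m) {
    if (cfg$sigma == 0) rep(1, m) else exp(stats::rnorm(m, 0, cfg$sigma))
  }
  amt_m <- 10^stats::runif(cfg$n_mrna_spikes, -11, -7)  # 4 decades
  spikes_mrna <- spikein_table(data.frame(
    id = sprintf("spike_mrna_%02d", seq_len(cfg$n_mrna_spikes)),
    amount = amt_m,
    signal = cfg$fpkm_gain * amt_m^cfg$spike_power *
      spike_noise(cfg$n_mrna_spikes),
    stringsAsFactors = FALSE))
  tiers <- 10^seq(-9, -4, length.out = 6L)
  amt_p <- rep(tiers, length.out = cfg$n_protein_spikes)
  nup <- pmax(1L, stats::rpois(cfg$n_protein_spikes,
                               2 + 2 * log10(amt_p / min(amt_p))))
  spikes_prot <- spikein_table(data.frame(
    id = sprintf("ups_%02d", seq_len(cfg$n_protein_spikes)),
    amount = amt_p,
    signal = cfg$ibaq_gain * amt_p^cfg$spike_power *
      spike_noise(cfg$n_protein_spikes),
    n_unique_peptides = nup,
    stringsAsFactors = FALSE))

  # --- amino-acid pools -------------------------------------------------------
  t_rel <- rsum / rsum[1L]
  aa <- c("Gly", "Ser", "Gln", "Asp", "Ala", "Arg", "Asn", "Cys", "Glu",
          "His", "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Thr", "Trp",
          "Tyr", "Val")
  pools <- matrix(NA_real_, nrow(conds), length(aa),
                  dimnames = list(conds$condition, aa))
  pools[, "Gly"] <- 1.5 * t_rel / mean(t_rel)
  pools[, "Ser"] <- 2.8 * t_rel / mean(t_rel)
  pools[, "Gln"] <- 166.7
  pools[, "Asp"] <- 12.4
  flat <- setdiff(aa, c("Gly", "Ser", "Gln", "Asp"))
  pools[, flat] <- rep(exp(stats::rnorm(length(flat), log(5), 1)),
                       each = nrow(conds))
  if (cfg$sigma > 0) {
    pools <- pools * exp(stats::rnorm(length(pools), 0, cfg$sigma / 4))
  }
  aa_pools <- data.frame(condition = conds$condition, pools,
                         check.names = FALSE, stringsAsFactors = FALSE)

  truth <- structure(list(
    params = params,
    mrna_true = mrna_true, protein_true = prot_true, ksp_true = ksp_true,
    conditions = conds, depth = depth,
    spike_law = list(power = cfg$spike_power, fpkm_gain = cfg$fpkm_gain,
                     ibaq_gain = cfg$ibaq_gain),
    rna_content_coef = c_rna,
    planted_k = 3L,  # two growth-slope regimes + one flat class
    class_fractions = cfg$class_fractions,
    config = cfg
  ), class = "SyntheticTruth")

  structure(list(
    mrna = expression_matrix(mrna_obs, "mmol_per_gDW", "mRNA"),
    protein = expression_matrix(prot_obs, "mmol_per_gDW", "protein"),
    mrna_fpkm = expression_matrix(fpkm, "FPKM", "mRNA"),
    protein_ibaq = expression_matrix(ibaq, "iBAQ", "protein"),
    design = design, aa_pools = aa_pools,
    spikes_mrna = spikes_mrna, spikes_protein = spikes_prot,
    contents = contents, truth = truth
  ), class = "ChemostatSimulation")
}

#' @export
print.ChemostatSimulation <- function(x, ...) {
  cat(sprintf(
    "ChemostatSimulation: %d genes, %d samples (%d conditions), sigma = %g\n",
    nrow(x$mrna$values), ncol(x$mrna$values),
    length(unique(x$design$condition)), x$truth$config$sigma))
  invisible(x)
}

#' Simulate a baseline/target perturbation pair for decoupling analysis
#'
#' Generates two matched single-condition datasets: a baseline (fast growth
#' on a preferred nitrogen source by default) and a target in which the
#' growth rate and nitrogen state change. For non-CCM genes the target is
#' the baseline scaled by `mu_target / mu_baseline` at both the mRNA and
#' translation-rate level, with the nitrogen factor applied (removed) at
#' the mRNA level and removed (applied) at the k_sP level when the
#' preferred-source status changes; CCM-like genes stay constant. This
#' mirrors the multiplicative null model of growth + nitrogen control, so
#' with `sigma = 0` and `n_specific = 0` the target equals the null-model
#' prediction exactly. On top of the physiological change, exactly
#' `n_specific` randomly chosen non-CCM genes receive a perturbation-specific
#' mRNA fold-change (`specific_fold` up for half, down for the other half),
#' with protein following through the unchanged translation rate.
#'
#' @param config A [simulation_config()]; `sigma`, `nitrogen_factor` and the
#'   per-gene parameter distributions are taken from it.
#' @param n_specific Number of perturbation-specific genes (0 allowed).
#' @param specific_fold Fold-change (> 1) of specific regulation.
#' @param seed Integer seed (defaults to `config$seed`).
#' @param mu_baseline,mu_target Growth rates of the two states, 1/h.
#' @param baseline_preferred,target_preferred Preferred-source status of the
#'   two states.
#' @return A `PerturbationPair` list: `baseline` and `target` (each with
#'   `mrna`, `protein` `ExpressionMatrix` and a `ConditionDesign`), and
#'   `truth` with per-gene labels (`"up"`, `"down"`, `"none"`), the CCM gene
#'   set, degradation rates, and the factors of the generating null model.
#' @export
simulate_perturbation_pair <- function(config = simulation_config(),
                                       n_specific = 50L,
                                       specific_fold = 4,
                                       seed = config$seed,
                                       mu_baseline = 0.2,
                                       mu_target = 0.1,
                                       baseline_preferred = TRUE,
                                       target_preferred = FALSE) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (specific_fold <= 1) stop("specific_fold must be > 1", call. = FALSE)
  if (mu_baseline <= 0 || mu_target <= 0) {
    stop("growth rates must be > 0", call. = FALSE)
  }
  with_seed(seed, {
    cfg <- config
    params <- draw_gene_params(cfg)
    n <- cfg$n_genes
    non_ccm <- which(params$class != "ccm_like")
    if (n_specific > length(non_ccm)) {
      stop("n_specific exceeds the number of non-CCM genes", call. = FALSE)
    }

    f <- cfg$nitrogen_factor
    fb <- if (baseline_preferred) f else 1
    ft <- if (target_preferred) f else 1
    is_ccm <- params$class == "ccm_like"

    # baseline state: mu-proportional law of the conceptual model
    mrna_b <- params$basal * ifelse(is_ccm, 1, mu_baseline / cfg$mu_ref * fb)
    ksp_b <- params$k0 * ifelse(is_ccm, 1, (mu_baseline / cfg$mu_ref) / fb)
    # target state before specific regulation
    mrna_t <- mrna_b * ifelse(is_ccm, 1, (mu_target / mu_baseline) * ft / fb)
    ksp_t <- ksp_b * ifelse(is_ccm, 1, (mu_target / mu_baseline) * fb / ft)

    label <- rep("none", n)
    if (n_specific > 0) {
      chosen <- sample(non_ccm, n_specific)
      n_up <- ceiling(n_specific / 2)
      up <- chosen[seq_len(n_up)]
      down <- setdiff(chosen, up)
      mrna_t[up] <- mrna_t[up] * specific_fold
      mrna_t[down] <- mrna_t[down] / specific_fold
      label[up] <- "up"
      label[down] <- "down"
    }
    prot_b <- ksp_b * mrna_b / (params$kdp + mu_baseline)
    prot_t <- ksp_t * mrna_t / (params$kdp + mu_target)

    mk_state <- function(mrna, prot, tag, mu, pref) {
      reps <- seq_len(cfg$replicates)
      noise <- function() {
        if (cfg$sigma == 0) matrix(1, n, length(reps))
        else matrix(exp(stats::rnorm(n * length(reps), 0, cfg$sigma)), n)
      }
      mk <- function(v, layer) {
        m <- v * noise()
        dimnames(m) <- list(params$gene, sprintf("%s_r%d", tag, reps))
        expression_matrix(m, "mmol_per_gDW", layer)
      }
      design <- condition_design(data.frame(
        sample = sprintf("%s_r%d", tag, reps), condition = tag, mu = mu,
        limitation = "carbon", n_source = if (pref) "NH4" else "Phe",
        preferred = pref, replicate = reps, stringsAsFactors = FALSE))
      list(mrna = mk(mrna, "mRNA"), protein = mk(prot, "protein"),
           design = design)
    }

    truth <- list(
      params = params, label = label,
      ccm_genes = params$gene[is_ccm],
      mrna_baseline_true = stats::setNames(mrna_b, params$gene),
      mrna_target_true = stats::setNames(mrna_t, params$gene),
      ksp_baseline_true = stats::setNames(ksp_b, params$gene),
      ksp_target_true = stats::setNames(ksp_t, params$gene),
      mu_baseline = mu_baseline, mu_target = mu_target,
      mrna_nitrogen_factor = ft / fb,
      ksp_nitrogen_factor = fb / ft,
      specific_fold = specific_fold
    )

    structure(list(
      baseline = mk_state(mrna_b, prot_b, "baseline", mu_baseline,
                          baseline_preferred),
      target = mk_state(mrna_t, prot_t, "target", mu_target,
                        target_preferred),
      truth = truth
    ), class = "PerturbationPair")
  })
}

#' Simulate protein and CDS sequences tied to a per-gene coupling score
#'
#' Generates random protein sequences in which the glutamine (Q) proportion
#' decreases with the gene's transcription-translation coupling score (for
#' example a protein-mRNA correlation), and back-translates them into CDS
#' sequences whose synonymous-codon choice is purine-biased for low-scoring
#' genes. Used to exercise the bracket-profile analyses on data with a
#' planted sequence-composition gradient.
#'
#' @param score Named numeric vector (gene -> coupling score).
#' @param length Protein length in residues.
#' @param q_range Range of the planted Q proportion (high at the lowest
#'   score, decaying to low at the highest).
#' @param seed Integer seed.
#' @return List with `protein` and `cds` [sequence_set()]s.
#' @export
simulate_sequences <- function(score, length = 400L,
                               q_range = c(0.03, 0.13), seed = 1L) {
  if (is.null(names(score))) stop("'score' must be named by gene", call. = FALSE)
  with_seed(seed, {
    u <- rank(score, ties.method = "average") / length(score)
    p_q <- q_range[2] - (q_range[2] - q_range[1]) * u
    aas <- aa_alphabet()
    gc_tab <- genetic_code()
    codon_map <- split(names(gc_tab), gc_tab)
    prot <- character(length(score))
    cds <- character(length(score))
    for (i in seq_along(score)) {
      w <- rep((1 - p_q[i]) / 19, 20)
      w[aas == "Q"] <- p_q[i]
      s <- sample(aas, length, replace = TRUE, prob = w)
      prot[i] <- paste(s, collapse = "")
      # purine preference in synonymous codon choice for low-score genes
      pur_w <- 1 + 2 * (1 - u[i])
      cds[i] <- paste(vapply(s, function(a) {
        cods <- codon_map[[a]]
        wts <- pur_w^vapply(strsplit(cods, ""), function(x)
          sum(x %in% c("A", "G")), numeric(1))
        sample(cods, 1L, prob = wts)
      }, character(1)), collapse = "")
    }
    names(prot) <- names(cds) <- names(score)
    list(protein = sequence_set(prot, "protein"),
         cds = sequence_set(cds, "CDS"))
  })
}
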