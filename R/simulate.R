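# Seeded synthetic paired-chain repertoire generator with ground truth.

MOUSE_TRBV <- c(
  "TRBV1", "TRBV2", "TRBV3", "TRBV4", "TRBV5", "TRBV12-1", "TRBV12-2",
  "TRBV13-1", "TRBV13-2", "TRBV13-3", "TRBV14", "TRBV15", "TRBV16",
  "TRBV17", "TRBV19", "TRBV20", "TRBV23", "TRBV26", "TRBV29", "TRBV31"
)
MOUSE_TRAV <- c(
  "TRAV1", "TRAV2", "TRAV3-3", "TRAV4-3", "TRAV5-1", "TRAV6-1", "TRAV7-2",
  "TRAV8-1", "TRAV9-1", "TRAV10", "TRAV11", "TRAV12-1", "TRAV13-1",
  "TRAV14-1", "TRAV15-1", "TRAV16", "TRAV17", "TRAV19", "TRAV21", "TRAV6-7"
)
MOUSE_TRBJ <- c("TRBJ1-1", "TRBJ1-4", "TRBJ2-1", "TRBJ2-5", "TRBJ2-7")
MOUSE_TRAJ <- c("TRAJ12", "TRAJ22", "TRAJ27", "TRAJ33", "TRAJ56")

#' Configuration for the synthetic repertoire generator
#'
#' The defaults emulate a six-mouse, three-group virus-specific CD8 T cell
#' cohort: two samples per infection type, 300 clones per sample with a
#' power-law clone-size distribution (acute-like samples less expanded at
#' `alpha = 3.0`, chronic-/latent-like more expanded at `alpha = 1.8`),
#' group-specific germline V-gene base profiles perturbed per sample by a
#' Dirichlet draw (concentration `kappa`), CDR3s with conserved C...F
#' flanks, per-cell transcriptional cluster labels whose target-cluster
#' log-odds shift by `beta1 * log(clone size)`, and chain-dropout/doublet
#' contamination.
#'
#' @param seed Integer base seed; all per-sample substreams derive from it.
#' @param samples Tibble with one row per sample: `sample_id`,
#'   `group_label`, `n_clones`, `law` (`"powerlaw"` or `"geometric"`),
#'   `alpha`, `q`, `max_size`.
#' @param kappa Dirichlet concentration controlling inter-sample similarity
#'   of V-gene usage within a group (larger = more similar).
#' @param trbv_genes,trav_genes Gene name spaces for the base profiles.
#' @param trb_lengths,tra_lengths CDR3 amino-acid length supports.
#' @param cluster_ids Transcriptional cluster labels.
#' @param cluster_baseline Baseline cluster probabilities (recycled /
#'   normalized to `cluster_ids`).
#' @param beta1 Expansion-bias coefficient: the log-odds of the group's
#'   target cluster are shifted by `beta1 * log(clone size)`.
#' @param target_clusters Named list mapping group label to the target
#'   cluster id(s) favoured by expanded clones.
#' @param p_drop_tra,p_drop_trb,p_extra_chain Per-cell contamination rates
#'   (chain dropout and doublet-like extra chains).
#' @param public_clone_rate Probability that a clone is copied into another
#'   sample (a planted public clone).
#' @return A `generator_config` list.
#' @export
generator_config <- function(
    seed = 1L,
    samples = default_cohort_samples(),
    kappa = 200,
    trbv_genes = MOUSE_TRBV,
    trav_genes = MOUSE_TRAV,
    trb_lengths = 12:17,
    tra_lengths = 10:16,
    cluster_ids = as.character(0:7),
    cluster_baseline = c(0.20, 0.15, 0.15, 0.12, 0.10, 0.10, 0.10, 0.08),
    beta1 = 0.8,
    target_clusters = list(acute = "1", chronic = "5", latent = "2"),
    p_drop_tra = 0.05,
    p_drop_trb = 0.05,
    p_extra_chain = 0.03,
    public_clone_rate = 0.01) {
  assert_cols(samples, c("sample_id", "group_label", "n_clones", "law",
                         "alpha", "q", "max_size"), "sample spec")
  if (anyDuplicated(samples$sample_id)) abort("duplicate sample_ids")
  if (any(samples$n_clones < 1)) abort("n_clones must be >= 1")
  if (length(cluster_ids) == 0) abort("cluster_ids must be non-empty")
  if (kappa <= 0) abort("kappa must be > 0")
  probs <- c(p_drop_tra, p_drop_trb, p_extra_chain, public_clone_rate)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  baseline <- rep_len(cluster_baseline, length(cluster_ids))
  baseline <- baseline / sum(baseline)

  groups <- unique(samples$group_label)
  cfg <- list(
    seed = as.integer(seed),
    samples = samples,
    germline = list(
      trbv_genes = trbv_genes, trav_genes = trav_genes, kappa = kappa,
      base_profiles = group_base_profiles(groups, trbv_genes, trav_genes)
    ),
    cdr3 = list(trb_lengths = trb_lengths, tra_lengths = tra_lengths),
    clusters = list(ids = cluster_ids, baseline = baseline,
                    beta1 = beta1, targets = target_clusters),
    contamination = list(p_drop_tra = p_drop_tra, p_drop_trb = p_drop_trb,
                         p_extra_chain = p_extra_chain),
    public_clone_rate = public_clone_rate
  )
  structure(cfg, class = "generator_config")
}

#' Default six-sample cohort specification
#'
#' Two samples per group; acute-like samples use a steeper clone-size
#' power law (`alpha = 3.0`, mostly singletons) than chronic-/latent-like
#' samples (`alpha = 1.8`, heavy-tailed expansion).
#'
#' @param n_clones Clones per sample (default 300).
#' @param max_size Clone-size truncation (default 1500 cells).
#' @return Tibble of per-sample generator settings.
#' @export
default_cohort_samples <- function(n_clones = 300L, max_size = 1500L) {
  tibble::tibble(
    sample_id = c("acute_m1", "acute_m2", "chronic_m1", "chronic_m2",
                  "latent_m1", "latent_m2"),
    group_label = rep(c("acute", "chronic", "latent"), each = 2),
    n_clones = as.integer(n_clones),
    law = "powerlaw",
    alpha = c(3.0, 3.0, 1.8, 1.8, 1.8, 1.8),
    q = NA_real_,
    max_size = as.integer(max_size)
  )
}

# deterministic, distinct skewed base profile per group: a geometric decay
# assigned to a group-specific rotation of the gene list
group_base_profiles <- function(groups, trbv_genes, trav_genes) {
  skew <- function(genes, rot) {
    w <- 0.8^(seq_along(genes) - 1)
    w <- w / sum(w)
    idx <- ((seq_along(genes) - 1 + rot) %% length(genes)) + 1
    setNames(w[order(idx)], genes)
  }
  out <- purrr::imap(setNames(groups, groups), function(g, nm) {
    rot <- (match(g, groups) - 1) * 7L
    list(trbv = skew(trbv_genes, rot), trav = skew(trav_genes, rot + 3L))
  })
  out
}

#' Draw a Dirichlet-perturbed germline profile
#'
#' Samples a per-sample V-gene frequency profile around a base profile with
#' concentration `kappa` (standard gamma-normalization construction).
#'
#' @param base Named numeric base profile (sums to 1).
#' @param kappa Concentration (> 0); larger values keep samples closer to
#'   the base.
#' @return Named numeric profile summing to 1.
#' @export
sample_germline_profile <- function(base, kappa) {
  if (kappa <= 0) abort("kappa must be > 0")
  g <- rgamma(length(base), shape = kappa * base, rate = 1)
  if (sum(g) == 0) g[which.max(base)] <- 1 # degenerate draw guard
  setNames(g / sum(g), names(base))
}

#' Sample clone sizes from a truncated power-law or geometric law
#'
#' Power law: `P(k) proportional to k^(-alpha)` on `1..max_size`.
#' Geometric: `P(k) proportional to q (1-q)^(k-1)` on `1..max_size`.
#'
#' @param S Number of clones (>= 1).
#' @param law `"powerlaw"` or `"geometric"`.
#' @param alpha Power-law exponent (> 1 required when `max_size` is
#'   infinite).
#' @param q Geometric success probability in (0, 1].
#' @param max_size Truncation bound (default 1500).
#' @return Integer vector of `S` clone sizes in `[1, max_size]`.
#' @export
sample_clone_sizes <- function(S, law = c("powerlaw", "geometric"),
                               alpha = NULL, q = NULL, max_size = 1500L) {
  law <- match.arg(law)
  if (S < 1) abort("S must be >= 1")
  if (law == "powerlaw") {
    if (is.null(alpha)) abort("alpha is required for the power law")
    if (!is.finite(max_size)) {
      if (alpha <= 1) abort("alpha <= 1 with unbounded max size is non-normalizable")
      max_size <- 10000L # practical support for the unbounded case
    }
    k <- seq_len(max_size)
    w <- k^(-alpha)
  } else {
    if (is.null(q)) abort("q is required for the geometric law")
    if (q <= 0 || q > 1) abort("q must lie in (0, 1]")
    if (q == 1) return(rep(1L, S))
    if (!is.finite(max_size)) max_size <- 10000L
    k <- seq_len(max_size)
    w <- q * (1 - q)^(k - 1)
  }
  sample(k, size = S, replace = TRUE, prob = w)
}

# per-clone cluster probabilities under the softmax expansion-bias model
cluster_probs <- function(size, baseline, ids, target_ids, beta1) {
  logits <- log(baseline)
  logits[ids %in% target_ids] <- logits[ids %in% target_ids] +
    beta1 * log(size)
  p <- exp(logits - max(logits))
  p / sum(p)
}

#' Cell-level target-cluster log odds ratio implied by planted clone sizes
#'
#' Under the generator's softmax model, the expected cell-level 2x2 table
#' (expanded vs lowly-expanded stratum, in vs out of the target cluster
#' set) is a deterministic function of the planted clone sizes; this
#' returns its log odds ratio — the estimand the association analysis
#' should recover.
#'
#' @param sizes Planted clone sizes.
#' @param baseline Baseline cluster probabilities.
#' @param ids Cluster ids.
#' @param target_ids Target cluster id(s).
#' @param beta1 Expansion-bias coefficient.
#' @return Implied log odds ratio (`NA` if a stratum is empty).
#' @export
implied_association_logor <- function(sizes, baseline, ids, target_ids,
                                      beta1) {
  tgt <- function(k) {
    sum(cluster_probs(k, baseline, ids, target_ids, beta1)[ids %in% target_ids])
  }
  exp_sizes <- sizes[sizes >= 2]
  low_sizes <- sizes[sizes == 1]
  if (length(exp_sizes) == 0 || length(low_sizes) == 0) return(NA_real_)
  e_in <- sum(exp_sizes * vapply(exp_sizes, tgt, numeric(1)))
  e_out <- sum(exp_sizes) - e_in
  l_in <- length(low_sizes) * tgt(1)
  l_out <- length(low_sizes) - l_in
  log((e_in / e_out) / (l_in / l_out))
}

#' Calibrate the expansion-bias coefficient to a target log odds ratio
#'
#' Solves for the `beta1` whose implied cell-level target-cluster log odds
#' ratio (see [implied_association_logor()]) equals `target_logor` for a
#' given set of planted clone sizes.
#'
#' @inheritParams implied_association_logor
#' @param target_logor Desired implied log odds ratio.
#' @return Calibrated `beta1`.
#' @export
calibrate_expansion_bias <- function(sizes, baseline, ids, target_ids,
                                     target_logor) {
  f <- function(b) {
    implied_association_logor(sizes, baseline, ids, target_ids, b) -
      target_logor
  }
  uniroot(f, interval = c(-10, 10), tol = 1e-9)$root
}

# one random CDR3: conserved C...F flanks, random in-frame nt backing
random_cdr3 <- function(len_aa) {
  inner <- sample(AA_ALPHABET, len_aa - 2L, replace = TRUE)
  aa <- paste(c("C", inner, "F"), collapse = "")
  nt <- paste(vapply(c("C", inner, "F"), function(a) {
    cods <- CODONS_BY_AA[[a]]
    cods[sample.int(length(cods), 1L)]
  }, character(1)), collapse = "")
  list(aa = aa, nt = nt)
}

new_key_registry <- function() new.env(parent = emptyenv())

# draw a clone's paired CDR3s, resampling on clonotype-key collision
draw_clone_cdr3 <- function(cfg, registry) {
  repeat {
    lb <- sample(cfg$cdr3$trb_lengths, 1L)
    la <- sample(cfg$cdr3$tra_lengths, 1L)
    b <- random_cdr3(lb)
    a <- random_cdr3(la)
    key <- paste(b$nt, a$nt, sep = "_")
    if (!exists(key, envir = registry, inherits = FALSE)) {
      assign(key, TRUE, envir = registry)
      return(list(cdr3b = b, cdr3a = a, key = key))
    }
  }
}

# emit the 10x-dialect contig rows + annotations for one clone's cells
emit_clone_cells <- function(cfg, sample_id, group_label, clone, size,
                             barcode_start) {
  ids <- cfg$clusters$ids
  targets <- cfg$clusters$targets[[group_label]] %||% ids[1]
  p <- cluster_probs(size, cfg$clusters$baseline, ids, targets,
                     cfg$clusters$beta1)
  barcodes <- sprintf("BC%07d-1", barcode_start + seq_len(size) - 1L)
  clusters <- sample(ids, size, replace = TRUE, prob = p)

  contigs <- tibble::tibble(
    barcode = rep(barcodes, each = 2L),
    is_cell = "True",
    contig_id = paste0(rep(barcodes, each = 2L), "_contig_",
                       rep(1:2, size)),
    high_confidence = "True",
    chain = rep(c("TRB", "TRA"), size),
    v_gene = rep(c(clone$trbv, clone$trav), size),
    d_gene = rep(c("TRBD1", "None"), size),
    j_gene = rep(c(clone$trbj, clone$traj), size),
    full_length = "True",
    productive = "True",
    cdr3 = rep(c(clone$cdr3b_aa, clone$cdr3a_aa), size),
    cdr3_nt = rep(c(clone$cdr3b_nt, clone$cdr3a_nt), size),
    umis = sample(2:12, 2L * size, replace = TRUE)
  )
  annotations <- tibble::tibble(
    barcode = barcodes, sample_id = sample_id,
    group_label = group_label, cluster_id = clusters
  )
  list(contigs = contigs, annotations = annotations)
}

# chain dropout / doublet contamination applied to a sample's contig table
apply_contamination <- function(contigs, cfg) {
  cont <- cfg$contamination
  if (nrow(contigs) == 0) return(contigs)
  barcodes <- unique(contigs$barcode)
  n <- length(barcodes)
  drop_a <- barcodes[stats::runif(n) < cont$p_drop_tra]
  drop_b <- barcodes[stats::runif(n) < cont$p_drop_trb]
  extra <- barcodes[stats::runif(n) < cont$p_extra_chain]

  out <- contigs |>
    dplyr::filter(!(.data$chain == "TRA" & .data$barcode %in% drop_a),
                  !(.data$chain == "TRB" & .data$barcode %in% drop_b))
  if (length(extra) > 0) {
    extras <- purrr::map_dfr(extra, function(bc) {
      c3 <- random_cdr3(sample(cfg$cdr3$trb_lengths, 1L))
      tibble::tibble(
        barcode = bc, is_cell = "True",
        contig_id = paste0(bc, "_contig_x"),
        high_confidence = "True", chain = "TRB",
        v_gene = sample(cfg$germline$trbv_genes, 1L),
        d_gene = "TRBD1",
        j_gene = sample(MOUSE_TRBJ, 1L),
        full_length = "True", productive = "True",
        cdr3 = c3$aa, cdr3_nt = c3$nt,
        umis = 1L
      )
    })
    out <- dplyr::bind_rows(out, extras)
  }
  dplyr::arrange(out, .data$barcode, .data$contig_id)
}

#' Generate one synthetic repertoire
#'
#' Draws clone sizes, V-gene pairs from the sample's Dirichlet-perturbed
#' group profile, unique paired CDR3s with in-frame nucleotide backing,
#' per-cell cluster labels from the expansion-bias softmax model, and
#' applies contamination last. Deterministic for a fixed config seed and
#' sample index.
#'
#' @param config A [generator_config()].
#' @param sample_index Row of `config$samples` to generate.
#' @param .registry Internal: shared clonotype-key registry ensuring
#'   cross-sample key uniqueness when called from [generate_cohort()].
#' @return List of `contigs` (10x-dialect tibble), `annotations` (per-cell
#'   tibble) and `truth` (planted clone table: `sample_id`, `group_label`,
#'   `clone_id`, `cdr3b_nt`, `cdr3a_nt`, `size`, `trbv`, `trav`,
#'   `is_public`).
#' @export
generate_repertoire <- function(config, sample_index,
                                .registry = new_key_registry()) {
  stopifnot(inherits(config, "generator_config"))
  spec <- config$samples[sample_index, ]
  set.seed(config$seed + sample_index * 1009L)

  sizes <- sample_clone_sizes(spec$n_clones, spec$law, alpha = spec$alpha,
                              q = spec$q, max_size = spec$max_size)
  base <- config$germline$base_profiles[[spec$group_label]]
  prof_b <- sample_germline_profile(base$trbv, config$germline$kappa)
  prof_a <- sample_germline_profile(base$trav, config$germline$kappa)

  clones <- purrr::map(seq_len(spec$n_clones), function(j) {
    cd <- draw_clone_cdr3(config, .registry)
    list(
      cdr3b_nt = cd$cdr3b$nt, cdr3a_nt = cd$cdr3a$nt,
      cdr3b_aa = cd$cdr3b$aa, cdr3a_aa = cd$cdr3a$aa,
      key = cd$key,
      trbv = sample(names(prof_b), 1L, prob = prof_b),
      trav = sample(names(prof_a), 1L, prob = prof_a),
      trbj = sample(MOUSE_TRBJ, 1L),
      traj = sample(MOUSE_TRAJ, 1L)
    )
  })

  barcode_start <- 1L
  pieces <- vector("list", spec$n_clones)
  for (j in seq_len(spec$n_clones)) {
    pieces[[j]] <- emit_clone_cells(config, spec$sample_id,
                                    spec$group_label, clones[[j]],
                                    sizes[j], barcode_start)
    barcode_start <- barcode_start + sizes[j]
  }
  contigs <- purrr::map_dfr(pieces, "contigs")
  annotations <- purrr::map_dfr(pieces, "annotations")
  contigs <- apply_contamination(contigs, config)

  truth <- tibble::tibble(
    sample_id = spec$sample_id,
    group_label = spec$group_label,
    clone_id = purrr::map_chr(clones, "key"),
    cdr3b_nt = purrr::map_chr(clones, "cdr3b_nt"),
    cdr3a_nt = purrr::map_chr(clones, "cdr3a_nt"),
    size = sizes,
    trbv = purrr::map_chr(clones, "trbv"),
    trav = purrr::map_chr(clones, "trav"),
    is_public = FALSE
  )
  list(contigs = contigs, annotations = annotations, truth = truth)
}

#' Generate a synthetic cohort with ground truth
#'
#' Generates every sample in the config, plants public clones by copying
#' clonotype keys across samples at `public_clone_rate`, and (optionally)
#' writes the cohort to disk in the same dialects the pipeline reads:
#' one 10x-dialect `<sample>_filtered_contig_annotations.csv` per sample,
#' a pooled `annotations.tsv`, and a `manifest.json` holding all planted
#' parameters and the true clone table.
#'
#' @param config A [generator_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return List with `contigs` (named list of per-sample tibbles),
#'   `annotations` (pooled tibble), `truth` (planted clone table across
#'   samples, including public copies), `public` (tibble of planted public
#'   clones: `clone_id`, `donor`, `recipient`, `size`), and `config`.
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (anyDuplicated(config$samples$sample_id)) abort("duplicate sample_ids")
  registry <- new_key_registry()
  n <- nrow(config$samples)
  reps <- purrr::map(seq_len(n), ~ generate_repertoire(config, .x,
                                                       .registry = registry))
  names(reps) <- config$samples$sample_id

  truth <- purrr::map_dfr(reps, "truth")
  public <- tibble::tibble(clone_id = character(), donor = character(),
                           recipient = character(), size = integer())

  if (config$public_clone_rate > 0 && n >= 2) {
    set.seed(config$seed + 999L)
    keys_by_sample <- split(truth$clone_id, truth$sample_id)
    for (i in seq_len(n)) {
      donor_id <- config$samples$sample_id[i]
      donor_truth <- reps[[i]]$truth
      copy <- stats::runif(nrow(donor_truth)) < config$public_clone_rate
      for (j in which(copy)) {
        rec_i <- sample(setdiff(seq_len(n), i), 1L)
        rec <- config$samples[rec_i, ]
        key <- donor_truth$clone_id[j]
        if (key %in% keys_by_sample[[rec$sample_id]]) next
        keys_by_sample[[rec$sample_id]] <-
          c(keys_by_sample[[rec$sample_id]], key)

        size <- sample_clone_sizes(1L, rec$law, alpha = rec$alpha,
                                   q = rec$q, max_size = rec$max_size)
        clone <- list(
          cdr3b_nt = donor_truth$cdr3b_nt[j],
          cdr3a_nt = donor_truth$cdr3a_nt[j],
          cdr3b_aa = translate_nt(donor_truth$cdr3b_nt[j]),
          cdr3a_aa = translate_nt(donor_truth$cdr3a_nt[j]),
          trbv = donor_truth$trbv[j], trav = donor_truth$trav[j],
          trbj = sample(MOUSE_TRBJ, 1L), traj = sample(MOUSE_TRAJ, 1L)
        )
        start <- 5000000L + nrow(reps[[rec_i]]$annotations)
        piece <- emit_clone_cells(config, rec$sample_id, rec$group_label,
                                  clone, size, start)
        piece$contigs <- apply_contamination(piece$contigs, config)
        reps[[rec_i]]$contigs <- dplyr::bind_rows(reps[[rec_i]]$contigs,
                                                  piece$contigs)
        reps[[rec_i]]$annotations <- dplyr::bind_rows(
          reps[[rec_i]]$annotations, piece$annotations)
        reps[[rec_i]]$truth <- dplyr::bind_rows(
          reps[[rec_i]]$truth,
          tibble::tibble(
            sample_id = rec$sample_id, group_label = rec$group_label,
            clone_id = key, cdr3b_nt = clone$cdr3b_nt,
            cdr3a_nt = clone$cdr3a_nt, size = size,
            trbv = clone$trbv, trav = clone$trav, is_public = TRUE
          )
        )
        public <- dplyr::bind_rows(public, tibble::tibble(
          clone_id = key, donor = donor_id,
          recipient = rec$sample_id, size = size
        ))
      }
    }
    truth <- purrr::map_dfr(reps, "truth")
  }

  annotations <- purrr::map_dfr(reps, "annotations")
  out <- list(
    contigs = purrr::map(reps, "contigs"),
    annotations = annotations,
    truth = truth,
    public = public,
    config = config
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (sid in names(out$contigs)) {
      readr::write_csv(
        out$contigs[[sid]],
        file.path(out_dir, paste0(sid, "_filtered_contig_annotations.csv")),
        progress = FALSE
      )
    }
    readr::write_tsv(annotations, file.path(out_dir, "annotations.tsv"),
                     progress = FALSE)
    manifest <- list(
      seed = config$seed,
      samples = config$samples,
      kappa = config$germline$kappa,
      beta1 = config$clusters$beta1,
      cluster_baseline = config$clusters$baseline,
      cluster_ids = config$clusters$ids,
      target_clusters = config$clusters$targets,
      contamination = config$contamination,
      public_clone_rate = config$public_clone_rate,
      clones = truth,
      public_clones = public
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         dataframe = "columns", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  out
}
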