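#' Configuration for the synthetic paired-design study generator
#'
#' The generator emulates a bilateral resistance-exercise microarray study:
#' each subject contributes one exercised-arm and one control-arm sample,
#' subjects fall into sex-by-recovery-time groups, per-gene residual
#' variances are drawn from a scaled-inverse-chi-square prior whose scale
#' may decrease log-linearly with mean log2 intensity, and differential
#' expression is planted probe-wise and concentrated into designated
#' ("loaded") gene sets.
#'
#' @param n_probes Number of probes on the simulated array.
#' @param groups Data frame with columns `sex`, `time`, `n_subjects`; one
#'   row per sex-by-time group. The default mirrors a 6 male / 8 female
#'   study split over 4 h and 24 h biopsy times (3+3 and 4+4 subjects).
#' @param intensity_range Range (log2 units) of probe mean intensities.
#' @param d0 True prior degrees of freedom of the variance prior (may be
#'   `Inf` for a point-mass prior).
#' @param s0_2 Prior variance scale at the centre of `intensity_range`
#'   (log2 units squared).
#' @param s0_slope Slope of `log(s0^2)` per log2-intensity unit; negative
#'   values give the variance-vs-intensity decrease typical of oligo
#'   arrays, `0` gives a constant prior scale.
#' @param subject_sd SD of the additive per-subject random effect.
#' @param de_fraction Fraction of probes carrying an exercise effect.
#' @param delta Magnitude of the planted exercised-minus-control log2 fold
#'   change (sign randomised per probe). A vector gives the menu of
#'   magnitudes, sampled uniformly per differential probe.
#' @param de_scope `"per_group"` ties each differential probe to a single
#'   sex-by-time condition; `"all"` applies the effect in every exercised
#'   arm.
#' @param baseline_de_fraction Fraction of probes with a sex main effect
#'   (visible in the male-vs-female baseline contrast).
#' @param baseline_delta Magnitude of the planted sex effect (log2).
#' @param n_sets Number of gene sets emitted by
#'   [generate_gene_sets_and_dag()].
#' @param set_size_range Inclusive range of set sizes.
#' @param loaded_fraction Fraction of sets loaded with planted effects.
#' @param within_set_de_fraction Target fraction of a loaded set's members
#'   drawn from the matching differential probes.
#' @param ct_noise_sd Technical SD of replicate qPCR Ct values.
#' @param seed Mandatory integer root seed; all randomness is derived from
#'   it through fixed per-component substreams.
#'
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_probes = 20000L,
                              groups = data.frame(
                                sex = c("M", "M", "F", "F"),
                                time = c("4h", "24h", "4h", "24h"),
                                n_subjects = c(3L, 3L, 4L, 4L),
                                stringsAsFactors = FALSE),
                              intensity_range = c(4, 14),
                              d0 = 4,
                              s0_2 = 0.05,
                              s0_slope = -0.2,
                              subject_sd = 0.3,
                              de_fraction = 0.05,
                              delta = 1,
                              de_scope = c("per_group", "all"),
                              baseline_de_fraction = 0.02,
                              baseline_delta = 1,
                              n_sets = 50L,
                              set_size_range = c(10L, 200L),
                              loaded_fraction = 0.2,
                              within_set_de_fraction = 0.8,
                              ct_noise_sd = 0.1,
                              seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` is mandatory", call. = FALSE)
  de_scope <- match.arg(de_scope)
  stopifnot(n_probes >= 1L, nrow(groups) >= 1L, all(groups$n_subjects >= 1L),
            diff(range(intensity_range)) >= 0, d0 > 0, s0_2 > 0,
            subject_sd >= 0, de_fraction >= 0, de_fraction <= 1,
            baseline_de_fraction >= 0, baseline_de_fraction <= 1,
            n_sets >= 1L, set_size_range[1L] >= 1L,
            set_size_range[2L] >= set_size_range[1L],
            loaded_fraction >= 0, loaded_fraction <= 1,
            within_set_de_fraction >= 0, within_set_de_fraction <= 1,
            ct_noise_sd >= 0)
  cfg <- list(n_probes = as.integer(n_probes), groups = groups,
              intensity_range = intensity_range, d0 = d0, s0_2 = s0_2,
              s0_slope = s0_slope, subject_sd = subject_sd,
              de_fraction = de_fraction, delta = delta, de_scope = de_scope,
              baseline_de_fraction = baseline_de_fraction,
              baseline_delta = baseline_delta, n_sets = as.integer(n_sets),
              set_size_range = as.integer(set_size_range),
              loaded_fraction = loaded_fraction,
              within_set_de_fraction = within_set_de_fraction,
              ct_noise_sd = ct_noise_sd, seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

# Fixed substream offsets: adding probes or sets must not perturb the
# random draws of unrelated components, so each component reseeds from the
# root seed plus its own offset (kept below 2^31).
substream <- function(config, k) {
  set.seed((config$seed + k * 99991L) %% 2147483647L)
}

s0_fun <- function(config) {
  centre <- mean(config$intensity_range)
  function(a) config$s0_2 * exp(config$s0_slope * (a - centre))
}

group_label <- function(sex, time) paste0(sex, "_", time)

# Per-probe ground truth, reproducible from (config, seed) alone so the
# gene-set generator can agree with the study generator without seeing it.
probe_truth <- function(config) {
  n <- config$n_probes
  substream(config, 1L)
  a <- stats::runif(n, config$intensity_range[1L], config$intensity_range[2L])
  s0 <- s0_fun(config)(a)
  sigma2 <- if (is.infinite(config$d0)) s0 else
    config$d0 * s0 / stats::rchisq(n, df = config$d0)
  probe_id <- sprintf("P%05d", seq_len(n))

  is_de <- rep(FALSE, n)
  delta <- numeric(n)
  condition <- rep(NA_character_, n)
  n_de <- floor(config$de_fraction * n)
  if (n_de > 0L) {
    de_idx <- sample.int(n, n_de)
    is_de[de_idx] <- TRUE
    mag <- if (length(config$delta) == 1L) config$delta else
      sample(config$delta, n_de, replace = TRUE)
    delta[de_idx] <- mag * sample(c(-1, 1), n_de, replace = TRUE)
    condition[de_idx] <- if (config$de_scope == "all") "all" else
      sample(group_label(config$groups$sex, config$groups$time),
             n_de, replace = TRUE)
  }

  is_sex_de <- rep(FALSE, n)
  sex_delta <- numeric(n)
  n_sex <- floor(config$baseline_de_fraction * n)
  if (n_sex > 0L) {
    pool <- which(!is_de)
    if (length(pool) < n_sex) pool <- seq_len(n)
    sex_idx <- sample(pool, n_sex)
    is_sex_de[sex_idx] <- TRUE
    sex_delta[sex_idx] <- config$baseline_delta *
      sample(c(-1, 1), n_sex, replace = TRUE)
  }

  data.frame(probe_id = probe_id, a = a, sigma2 = sigma2, is_de = is_de,
             delta = delta, direction = sign(delta), condition = condition,
             is_sex_de = is_sex_de, sex_delta = sex_delta,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic paired expression study with ground truth
#'
#' Simulates `value = a_g + subject effect + sex effect + arm effect +
#' N(0, sigma_g^2 / 2)` where `sigma_g^2 ~ d0 * s0^2(a_g) / chisq(d0)`
#' (scaled-inverse-chi-square, intensity-dependent scale). `sigma_g^2` is
#' the gene's residual variance at the within-subject contrast level:
#' each arm contributes half of it, so exercised-minus-control
#' differences have variance exactly `sigma_g^2` and the fitted paired
#' residual variances follow the scaled F distribution the
#' empirical-Bayes model assumes. The arm effect
#' `delta_g` applies to exercised-arm samples of differential probes in
#' their assigned condition, and the sex effect applies to every sample of
#' male subjects so that it cancels from within-subject contrasts but is
#' seen by the baseline male-vs-female comparison.
#'
#' @param config A [simulation_config()].
#' @return List with elements `study` (an [expression_study()]) and
#'   `truth` (per-probe data frame: intensity, true variance, planted
#'   effects and their conditions).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (any(config$groups$n_subjects < 2L))
    stop("paired groups need n_subjects >= 2", call. = FALSE)
  truth <- probe_truth(config)
  g <- config$groups
  subj <- do.call(rbind, lapply(seq_len(nrow(g)), function(i)
    data.frame(subject_id = sprintf("%s_s%d", group_label(g$sex[i], g$time[i]),
                                    seq_len(g$n_subjects[i])),
               sex = g$sex[i], time = g$time[i], stringsAsFactors = FALSE)))
  design <- do.call(rbind, lapply(c("exercised", "control"), function(arm)
    data.frame(sample_id = paste0(subj$subject_id,
                                  ifelse(arm == "exercised", "_ex", "_ctl")),
               subject_id = subj$subject_id, sex = subj$sex, arm = arm,
               time = subj$time, stringsAsFactors = FALSE)))
  design <- design[order(design$subject_id, design$arm), , drop = FALSE]
  rownames(design) <- NULL

  substream(config, 2L)
  subj_eff <- stats::rnorm(nrow(subj), 0, config$subject_sd)
  names(subj_eff) <- subj$subject_id

  n <- config$n_probes
  m <- nrow(design)
  substream(config, 3L)
  # sigma2 is defined at the within-subject contrast level; each arm
  # contributes half, so exercised-minus-control differences have
  # variance sigma2 and s2/s0^2(a) is marginally F(d, d0).
  noise <- matrix(stats::rnorm(n * m), n, m) * sqrt(truth$sigma2 / 2)

  vals <- matrix(truth$a, n, m) + noise
  vals <- vals + rep(subj_eff[design$subject_id], each = n)
  male <- design$sex == "M"
  if (any(truth$is_sex_de) && any(male))
    vals[, male] <- vals[, male] + truth$sex_delta
  ex <- which(design$arm == "exercised")
  for (j in ex) {
    lab <- group_label(design$sex[j], design$time[j])
    hit <- truth$is_de & (truth$condition == "all" | truth$condition == lab)
    vals[hit, j] <- vals[hit, j] + truth$delta[hit]
  }
  dimnames(vals) <- list(truth$probe_id, design$sample_id)
  list(study = expression_study(vals, design), truth = truth)
}

#' Generate gene sets (GMT) and a toy term DAG with ground truth
#'
#' Emits `n_sets` sets over the simulated probe universe: "loaded" sets
#' whose members are drawn mostly from differential probes of one
#' condition and direction, null sets drawn uniformly, and a structured
#' tail used to exercise redundancy collapsing -- one (parent, single
#' child) pair with membership overlap >= 0.9 and one (parent, two
#' siblings) triple. Reproducible from the same `(config, seed)` as
#' [generate_study()].
#'
#' @param config A [simulation_config()].
#' @return List with `sets` (a `gene_set_collection`), `dag` (a
#'   `term_dag` with child-to-parent edges among the structured terms) and
#'   `truth` (per-set data frame: role, loaded flag, condition, expected
#'   direction).
#' @export
generate_gene_sets_and_dag <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$set_size_range[2L] > config$n_probes)
    stop("requested set size exceeds the probe universe", call. = FALSE)
  truth <- probe_truth(config)
  universe <- truth$probe_id
  substream(config, 5L)

  n_structured <- 5L
  if (config$n_sets < n_structured + 1L)
    stop("n_sets must be at least ", n_structured + 1L, call. = FALSE)
  n_loaded <- min(round(config$loaded_fraction * config$n_sets),
                  config$n_sets - n_structured)
  n_null <- config$n_sets - n_loaded - n_structured

  combos <- expand.grid(condition = unique(stats::na.omit(truth$condition)),
                        direction = c(1, -1), stringsAsFactors = FALSE)
  ids <- sprintf("T%03d", seq_len(config$n_sets))
  sets <- vector("list", config$n_sets)
  names(sets) <- ids
  set_truth <- data.frame(set_id = ids, role = "null", is_loaded = FALSE,
                          condition = NA_character_,
                          direction = NA_character_,
                          stringsAsFactors = FALSE)

  sizes <- sample(seq(config$set_size_range[1L], config$set_size_range[2L]),
                  config$n_sets, replace = TRUE)
  k <- 0L
  for (i in seq_len(n_loaded)) {
    k <- k + 1L
    cc <- combos[((i - 1L) %% nrow(combos)) + 1L, ]
    pool <- which(truth$is_de & truth$condition == cc$condition &
                    truth$direction == cc$direction)
    if (!length(pool))
      stop("no differential probes available for condition ", cc$condition,
           call. = FALSE)
    size <- sizes[k]
    n_sig <- min(round(config$within_set_de_fraction * size), length(pool))
    bg <- sample(which(!truth$is_de), size - n_sig)
    sets[[k]] <- universe[sort(c(sample(pool, n_sig), bg))]
    set_truth$role[k] <- "loaded"
    set_truth$is_loaded[k] <- TRUE
    set_truth$condition[k] <- cc$condition
    set_truth$direction[k] <- if (cc$direction > 0) "up" else "down"
  }
  for (i in seq_len(n_null)) {
    k <- k + 1L
    sets[[k]] <- universe[sort(sample.int(config$n_probes, sizes[k]))]
  }

  # structured tail: parent with one near-identical child, then a parent
  # with two sibling subsets
  null_pool <- which(!truth$is_de)
  p1 <- sort(sample(null_pool, 50L))
  c1 <- sort(sample(p1, 45L))                       # Jaccard 0.9
  p2 <- sort(sample(setdiff(null_pool, p1), 40L))
  s1 <- sort(sample(p2, 30L))                       # Jaccard 0.75
  s2 <- sort(sample(p2, 30L))
  structured <- list(p1, c1, p2, s1, s2)
  roles <- c("parent_of_child", "child", "parent_of_siblings",
             "sibling", "sibling")
  for (i in seq_len(n_structured)) {
    k <- k + 1L
    sets[[k]] <- universe[structured[[i]]]
    set_truth$role[k] <- roles[i]
  }
  str_ids <- ids[(config$n_sets - n_structured + 1L):config$n_sets]
  edges <- data.frame(child = c(str_ids[2L], str_ids[4L], str_ids[5L]),
                      parent = c(str_ids[1L], str_ids[3L], str_ids[3L]),
                      stringsAsFactors = FALSE)
  list(sets = gene_set_collection(sets,
                                  descriptions = paste("synthetic set",
                                                       set_truth$role)),
       dag = term_dag(edges, nodes = ids),
       truth = set_truth)
}

#' Generate a synthetic duplicate-well qPCR Ct panel
#'
#' Emulates relative quantification at amplification efficiency exactly 2:
#' each target gene gets duplicate Ct wells and matched reference-gene
#' wells per subject and condition; a per-sample loading shift is shared
#' by target and reference wells (and so cancels under reference
#' normalization), and the exercised-arm target Ct is lowered by the
#' planted log2 fold change.
#'
#' @param truth Per-probe truth data frame from [generate_study()].
#' @param genes Probe ids to assay; default samples `n_genes` probes
#'   (differential probes first, topped up with null probes).
#' @param n_genes Number of genes when `genes` is `NULL`.
#' @param n_subject_pairs Subjects (each with exercised and control arms).
#' @param noise_sd Technical SD of each replicate Ct.
#' @param seed Integer seed.
#' @return Data frame with columns `gene`, `subject`, `condition`,
#'   `well_role` (`"target"`/`"reference"`), `replicate`, `ct`, plus the
#'   per-gene planted log2 fold as attribute `"log2_fold"`.
#' @export
generate_qpcr_panel <- function(truth, genes = NULL, n_genes = 10L,
                                n_subject_pairs = 4L, noise_sd = 0.1,
                                seed = 1L) {
  stopifnot(n_genes >= 1L, n_subject_pairs >= 1L, noise_sd >= 0)
  set.seed(seed)
  if (is.null(genes)) {
    de <- truth$probe_id[truth$is_de]
    genes <- c(de[seq_len(min(length(de), n_genes))],
               truth$probe_id[!truth$is_de][seq_len(max(0L, n_genes -
                                                          length(de)))])
    genes <- genes[seq_len(n_genes)]
  }
  ti <- match(genes, truth$probe_id)
  if (anyNA(ti)) stop("unknown gene id in qPCR panel request", call. = FALSE)
  delta <- truth$delta[ti]
  base_ct <- 30 - truth$a[ti] / 2
  subjects <- sprintf("q_s%d", seq_len(n_subject_pairs))
  grid <- expand.grid(replicate = 1:2,
                      well_role = c("target", "reference"),
                      condition = c("exercised", "control"),
                      subject = subjects, gene = genes,
                      stringsAsFactors = FALSE)
  load_shift <- stats::rnorm(n_subject_pairs * 2L, 0, 0.5)
  names(load_shift) <- paste(rep(subjects, each = 2L),
                             c("exercised", "control"))
  gi <- match(grid$gene, genes)
  ct <- ifelse(grid$well_role == "reference", 18,
               base_ct[gi] - ifelse(grid$condition == "exercised",
                                    delta[gi], 0)) +
    load_shift[paste(grid$subject, grid$condition)] +
    stats::rnorm(nrow(grid), 0, noise_sd)
  out <- data.frame(gene = grid$gene, subject = grid$subject,
                    condition = grid$condition, well_role = grid$well_role,
                    replicate = grid$replicate, ct = ct,
                    stringsAsFactors = FALSE)
  attr(out, "log2_fold") <- stats::setNames(delta, genes)
  out
}
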