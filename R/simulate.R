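# Synthetic paired-data generator with known ground truth. The generator
# lives on the log2 scale the pipeline consumes (Gaussian model): miRNA
# values ~ Normal(8, 1) log2 units, target mRNAs are linear negative
# functions of their regulator plus noise, and prediction databases list
# true pairs with a given sensitivity plus uniformly drawn decoy pairs.
# A secondary count-scale emitter exists for the median filter.

#' Simulation configuration
#'
#' Defaults encode the standard validation scenario: 300 miRNAs x 3000
#' mRNAs, 30 control + 30 case samples, 500 planted regulations at
#' `beta = 0.75` and unit noise (population correlation -0.6 for planted
#' pairs, see [expected_rho()]), databases that list a true pair with
#' probability 0.9 plus 5x as many decoy pairs.
#'
#' @param n_mirna,n_mrna feature counts.
#' @param n_control,n_case samples per group.
#' @param n_true_pairs planted regulations; each target mRNA is regulated
#'   by exactly one miRNA, so this may not exceed `n_mrna`.
#' @param beta regulation strength (target log2 units per miRNA log2 unit).
#' @param noise_sd residual sd of target mRNAs (log2 units).
#' @param de_fraction fraction of miRNAs (and of non-target mRNAs) shifted
#'   between groups.
#' @param de_shift group shift magnitude (log2 units, random sign).
#' @param db_sensitivity probability that a database lists a true pair.
#' @param db_decoy_rate decoy pairs per database, as a multiple of
#'   `n_true_pairs`.
#' @param n_databases number of databases to emit.
#' @param seed RNG seed; everything is reproducible from it.
#' @export
simulation_config <- function(n_mirna = 300L, n_mrna = 3000L,
                              n_control = 30L, n_case = 30L,
                              n_true_pairs = 500L, beta = 0.75,
                              noise_sd = 1, de_fraction = 0.2, de_shift = 1,
                              db_sensitivity = 0.9, db_decoy_rate = 5,
                              n_databases = 2L, seed = 1L) {
  cfg <- list(n_mirna = as.integer(n_mirna), n_mrna = as.integer(n_mrna),
              n_control = as.integer(n_control), n_case = as.integer(n_case),
              n_true_pairs = as.integer(n_true_pairs), beta = beta,
              noise_sd = noise_sd, de_fraction = de_fraction,
              de_shift = de_shift, db_sensitivity = db_sensitivity,
              db_decoy_rate = db_decoy_rate, n_databases = as.integer(n_databases),
              seed = as.integer(seed))
  if (cfg$n_true_pairs > cfg$n_mrna)
    stop("infeasible config: n_true_pairs exceeds n_mrna ",
         "(each target mRNA has one regulator)")
  if (cfg$n_true_pairs > cfg$n_mirna * cfg$n_mrna)
    stop("infeasible config: more true pairs than possible pairs")
  if (cfg$noise_sd < 0 || cfg$de_shift < 0) stop("sd and shift must be >= 0")
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1 ||
      cfg$db_sensitivity < 0 || cfg$db_sensitivity > 1)
    stop("fractions must lie in [0, 1]")
  n_decoys <- round(cfg$db_decoy_rate * cfg$n_true_pairs)
  if (n_decoys > cfg$n_mirna * cfg$n_mrna - cfg$n_true_pairs)
    stop("infeasible config: not enough non-true pairs for the decoys")
  class(cfg) <- "sim_config"
  cfg
}

#' Population correlation of a planted pair
#'
#' Closed form for the simulated linear regulation model:
#' `-beta * mirna_sd / sqrt(beta^2 * mirna_sd^2 + noise_sd^2)`.
#'
#' @param beta regulation strength.
#' @param noise_sd residual sd.
#' @param mirna_sd sd of miRNA values (1 in the generator, absent a group
#'   shift).
#' @export
expected_rho <- function(beta, noise_sd, mirna_sd = 1) {
  -beta * mirna_sd / sqrt(beta^2 * mirna_sd^2 + noise_sd^2)
}

#' Simulate a paired expression dataset with known ground truth
#'
#' @param cfg configuration from [simulation_config()].
#' @return list with `dataset` (a [align_dataset()]-style `mir_dataset`),
#'   `truth` (list: `true_pairs` data.frame, `de_mirnas`, `de_mrnas`) and
#'   `databases` (list of [target_db()] objects).
#' @export
simulate_dataset <- function(cfg = simulation_config()) {
  if (!inherits(cfg, "sim_config")) stop("'cfg' must come from simulation_config()")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  n_samp <- cfg$n_control + cfg$n_case
  samples <- c(sprintf("ctrl_%03d", seq_len(cfg$n_control)),
               sprintf("case_%03d", seq_len(cfg$n_case)))
  is_case <- rep(c(FALSE, TRUE), c(cfg$n_control, cfg$n_case))
  mirna_ids <- sprintf("miR-%04d", seq_len(cfg$n_mirna))
  mrna_ids <- sprintf("gene-%05d", seq_len(cfg$n_mrna))

  M <- matrix(stats::rnorm(cfg$n_mirna * n_samp, mean = 8, sd = 1),
              nrow = cfg$n_mirna, dimnames = list(mirna_ids, samples))
  de_mirnas <- sort(sample(mirna_ids, round(cfg$de_fraction * cfg$n_mirna)))
  if (length(de_mirnas)) {
    signs <- sample(c(-1, 1), length(de_mirnas), replace = TRUE)
    M[de_mirnas, is_case] <- M[de_mirnas, is_case] + signs * cfg$de_shift
  }

  target_mrnas <- sample(mrna_ids, cfg$n_true_pairs)
  regulators <- sample(mirna_ids, cfg$n_true_pairs, replace = TRUE)
  true_pairs <- data.frame(miRNA = regulators, mRNA = target_mrnas,
                           stringsAsFactors = FALSE)

  G <- matrix(stats::rnorm(cfg$n_mrna * n_samp, mean = 8, sd = 1),
              nrow = cfg$n_mrna, dimnames = list(mrna_ids, samples))
  free <- setdiff(mrna_ids, target_mrnas)
  de_mrnas <- sort(sample(free, round(cfg$de_fraction * length(free))))
  if (length(de_mrnas)) {
    signs <- sample(c(-1, 1), length(de_mrnas), replace = TRUE)
    G[de_mrnas, is_case] <- G[de_mrnas, is_case] + signs * cfg$de_shift
  }
  # planted regulation: target = baseline - beta * regulator + noise,
  # baseline 8*(1+beta) keeps the marginal mean at 8 log2 units
  G[target_mrnas, ] <- 8 * (1 + cfg$beta) - cfg$beta * M[regulators, ] +
    matrix(stats::rnorm(cfg$n_true_pairs * n_samp, sd = cfg$noise_sd),
           nrow = cfg$n_true_pairs)

  pheno <- phenotype_table(samples, ifelse(is_case, "case", "control"),
                           control = "control", case = "case")
  ds <- align_dataset(expression_matrix(M, "log2"),
                      expression_matrix(G, "log2"), pheno)

  true_keys <- pair_key(true_pairs$miRNA, true_pairs$mRNA)
  n_decoys <- round(cfg$db_decoy_rate * cfg$n_true_pairs)
  databases <- lapply(seq_len(cfg$n_databases), function(b) {
    listed <- stats::runif(cfg$n_true_pairs) < cfg$db_sensitivity
    dec <- draw_decoys(cfg, true_keys, n_decoys, mirna_ids, mrna_ids)
    target_db(c(true_pairs$miRNA[listed], dec$miRNA),
              c(true_pairs$mRNA[listed], dec$mRNA),
              sprintf("synthDB_%d", b))
  })
  list(dataset = ds,
       truth = list(true_pairs = true_pairs, de_mirnas = de_mirnas,
                    de_mrnas = de_mrnas),
       databases = databases)
}

# decoy pairs drawn uniformly from non-true pairs, without replacement
draw_decoys <- function(cfg, true_keys, n_decoys, mirna_ids, mrna_ids) {
  if (n_decoys == 0L)
    return(data.frame(miRNA = character(), mRNA = character()))
  total <- as.double(cfg$n_mirna) * cfg$n_mrna
  got <- character(0)
  while (length(got) < n_decoys) {
    idx <- unique(ceiling(stats::runif(2L * (n_decoys - length(got))) * total))
    i <- ((idx - 1) %/% cfg$n_mrna) + 1
    j <- ((idx - 1) %% cfg$n_mrna) + 1
    keys <- pair_key(mirna_ids[i], mrna_ids[j])
    keys <- setdiff(keys, c(true_keys, got))
    got <- c(got, keys)
  }
  got <- got[seq_len(n_decoys)]
  sp <- strsplit(got, "\r", fixed = TRUE)
  data.frame(miRNA = vapply(sp, `[[`, "", 1L),
             mRNA = vapply(sp, `[[`, "", 2L), stringsAsFactors = FALSE)
}

#' Simulate a raw-count matrix (Poisson-lognormal)
#'
#' Count-scale emitter for exercising the median expression filter: counts
#' are Poisson draws around feature-specific lognormal means.
#'
#' @param n_features,n_samples dimensions.
#' @param log_mean,log_sd natural-log parameters of the per-feature mean.
#' @param seed RNG seed.
#' @export
simulate_counts <- function(n_features = 100L, n_samples = 20L,
                            log_mean = 3, log_sd = 2, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  mu <- stats::rlnorm(n_features, meanlog = log_mean, sdlog = log_sd)
  m <- matrix(stats::rpois(n_features * n_samples, lambda = rep(mu, n_samples)),
              nrow = n_features,
              dimnames = list(sprintf("feat_%04d", seq_len(n_features)),
                              sprintf("s%03d", seq_len(n_samples))))
  expression_matrix(m, "raw_counts")
}

#' Write a simulated scenario as the standard pipeline input files
#'
#' Emits `mirna.tsv`, `mrna.tsv`, `phenotype.tsv`, one `db_<name>.tsv` per
#' database and `true_pairs.tsv` into a directory.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named file paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    mirna = file.path(dir, "mirna.tsv"),
    mrna = file.path(dir, "mrna.tsv"),
    pheno = file.path(dir, "phenotype.tsv")
  )
  write_expression(sim$dataset$mirna, paths[["mirna"]])
  write_expression(sim$dataset$mrna, paths[["mrna"]])
  ph <- data.frame(sample = names(sim$dataset$pheno),
                   group = as.character(sim$dataset$pheno))
  utils::write.table(ph, paths[["pheno"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (db in sim$databases) {
    p <- file.path(dir, paste0("db_", db$name, ".tsv"))
    write_target_db(db, p)
    paths[[paste0("db_", db$name)]] <- p
  }
  paths[["true_pairs"]] <- file.path(dir, "true_pairs.tsv")
  utils::write.table(sim$truth$true_pairs, paths[["true_pairs"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
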