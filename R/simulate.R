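#' Configuration of the synthetic mutation-data generator
#'
#' The generator emulates a labeled driver/passenger missense set of the
#' kind assembled from somatic-mutation and polymorphism databases, with
#' class signal planted mechanistically per channel:
#'
#' * `aarc`/`ssm` — class-dependent substitution preferences: driver
#'   mutations are drawn toward radical substitutions (large hydropathy
#'   change), passengers toward conservative ones, with log-weight
#'   proportional to `effect_size`. Both encoder families read the same
#'   wild/mutant pair, so the two channels gain signal jointly.
#' * `pss` — class-dependent dipeptide bias: proteins carrying driver
#'   mutations are generated from a first-order chain enriched for
#'   within-group (6-letter alphabet) residue pairs.
#' * `af` — annotated features with class-shifted parameters: three numeric
#'   features with driver means shifted by `effect_size` standard
#'   deviations, three binary features with the driver rate shifted by
#'   `effect_size` on the logit scale; the remaining 23 schema features are
#'   class-independent noise.
#'
#' With `effect_size = 0` every channel is class-independent and downstream
#' accuracy is at chance.
#'
#' @param n_proteins Number of proteins (default 24; split between class
#'   pools when `pss` is informative).
#' @param seq_len_range Min/max sequence length (default 80-160).
#' @param n_driver,n_passenger Mutations per class (default 200 each, the
#'   balanced-design default; skew them to emulate imbalanced test sets).
#' @param informative_channels Subset of `c("aarc", "ssm", "pss", "af")`
#'   (default `c("aarc", "ssm", "af")`).
#' @param effect_size Class separation in feature-sigma units (default 2).
#' @param af_missing_rate Missingness rate of binary annotated features
#'   (default 0.1).
#' @param seed RNG seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 24, seq_len_range = c(80, 160),
                       n_driver = 200, n_passenger = 200,
                       informative_channels = c("aarc", "ssm", "af"),
                       effect_size = 2, af_missing_rate = 0.1, seed = 1) {
  if (n_proteins < 2 || n_driver < 1 || n_passenger < 1) {
    stop_config("counts must be positive (and n_proteins >= 2)")
  }
  if (effect_size < 0) stop_config("effect_size must be >= 0")
  if (af_missing_rate < 0 || af_missing_rate > 1) {
    stop_config("af_missing_rate must be in [0, 1]")
  }
  bad <- setdiff(informative_channels, c("aarc", "ssm", "pss", "af"))
  if (length(bad) > 0L) {
    stop_config(sprintf("unknown channel(s): %s", paste(bad, collapse = ", ")))
  }
  if (length(informative_channels) == 0L && effect_size > 0) {
    stop_config("effect_size > 0 requires at least one informative channel")
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 seq_len_range = as.integer(seq_len_range),
                 n_driver = as.integer(n_driver),
                 n_passenger = as.integer(n_passenger),
                 informative_channels = informative_channels,
                 effect_size = effect_size,
                 af_missing_rate = af_missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Planted AF features: first 3 binary and first 3 numeric of the default
# schema carry the class signal when the af channel is informative.
PLANTED_AF_BINARY <- sprintf("af.bin%02d", 1:3)
PLANTED_AF_NUMERIC <- sprintf("af.num%02d", 1:3)

simulate_protein <- function(len, within_group_boost = 0) {
  groups <- six_letter_alphabet()[AA20]
  seq_chars <- character(len)
  seq_chars[1] <- sample(AA20, 1L)
  if (within_group_boost == 0) {
    seq_chars[-1] <- sample(AA20, len - 1L, replace = TRUE)
  } else {
    for (i in 2:len) {
      w <- exp(within_group_boost * (groups == groups[[seq_chars[i - 1L]]]))
      seq_chars[i] <- sample(AA20, 1L, prob = w)
    }
  }
  paste(seq_chars, collapse = "")
}

#' Simulate a labeled mutation dataset with planted class structure
#'
#' See [sim_config()] for the generative model. Signal is planted
#' mechanistically — through substitution choices, source sequences, and
#' annotated values — so the feature encoders themselves are exercised, not
#' bypassed. Deterministic given the config seed.
#'
#' @param cfg A [sim_config()].
#' @return List with elements `dataset` (a `mutation_dataset` whose mutation
#'   table includes labels and the 29 annotated columns) and `truth` (the
#'   ground-truth record: informative channels, planted AF feature names,
#'   substitution property, and sequence-bias description).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  ch <- cfg$informative_channels
  eff <- cfg$effect_size
  pss_on <- "pss" %in% ch && eff > 0
  sub_on <- any(c("aarc", "ssm") %in% ch) && eff > 0
  af_on <- "af" %in% ch && eff > 0

  # --- proteins ---------------------------------------------------------
  ids <- sprintf("prot%02d", seq_len(cfg$n_proteins))
  lens <- sample(seq(cfg$seq_len_range[1], cfg$seq_len_range[2]),
                 cfg$n_proteins, replace = TRUE)
  driver_pool <- if (pss_on) seq_len(floor(cfg$n_proteins / 2)) else seq_len(cfg$n_proteins)
  passenger_pool <- if (pss_on) setdiff(seq_len(cfg$n_proteins), driver_pool) else seq_len(cfg$n_proteins)
  boost <- if (pss_on) 0.12 * eff else 0
  proteins <- setNames(vapply(seq_len(cfg$n_proteins), function(i) {
    simulate_protein(lens[i], if (i %in% driver_pool && pss_on) boost else 0)
  }, character(1)), ids)

  # --- mutation sites: unique (protein, position) pairs per pool --------
  draw_sites <- function(pool, n) {
    all_sites <- do.call(rbind, lapply(pool, function(i) {
      data.frame(protein_id = ids[i], position = seq_len(lens[i]))
    }))
    if (n > nrow(all_sites)) {
      stop_config("not enough protein positions for the requested mutation count")
    }
    all_sites[sample.int(nrow(all_sites), n), , drop = FALSE]
  }
  kd <- unclass(default_property_scales()[["KYTJ820101"]])
  kd_dist <- abs(outer(kd, kd, "-")) / sd(kd)
  pick_mutant <- function(wild, class) {
    others <- setdiff(AA20, wild)
    if (!sub_on) return(sample(others, 1L))
    d <- kd_dist[wild, others]
    w <- if (class == "driver") exp(eff * 0.7 * d) else exp(-eff * 0.7 * d)
    sample(others, 1L, prob = w)
  }
  make_rows <- function(class, sites) {
    n <- nrow(sites)
    wild <- substr(proteins[sites$protein_id], sites$position, sites$position)
    mutant <- vapply(seq_len(n), function(i) pick_mutant(wild[i], class), character(1))
    data.frame(protein_id = sites$protein_id, position = sites$position,
               wild = unname(wild), mutant = mutant, label = class,
               stringsAsFactors = FALSE)
  }
  # with disjoint class pools sites are drawn per pool; with a shared pool
  # they are drawn jointly so no two mutations hit the same site
  if (pss_on) {
    driver_sites <- draw_sites(driver_pool, cfg$n_driver)
    passenger_sites <- draw_sites(passenger_pool, cfg$n_passenger)
  } else {
    all_sites <- draw_sites(driver_pool, cfg$n_driver + cfg$n_passenger)
    driver_sites <- all_sites[seq_len(cfg$n_driver), , drop = FALSE]
    passenger_sites <- all_sites[cfg$n_driver + seq_len(cfg$n_passenger), , drop = FALSE]
  }
  rows <- rbind(make_rows("driver", driver_sites),
                make_rows("passenger", passenger_sites))

  # --- annotated features ----------------------------------------------
  schema <- default_af_schema()
  n <- nrow(rows)
  is_driver <- rows$label == "driver"
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    if (schema$kind[i] == "binary") {
      p <- rep(0.25, n)
      if (af_on && nm %in% PLANTED_AF_BINARY) {
        p[is_driver] <- stats::plogis(stats::qlogis(0.25) + eff)
      }
      v <- rbinom(n, 1L, p)
      v[runif(n) < cfg$af_missing_rate] <- NA
      rows[[nm]] <- v
    } else {
      mu <- rep(0, n)
      if (af_on && nm %in% PLANTED_AF_NUMERIC) mu[is_driver] <- eff
      rows[[nm]] <- round(rnorm(n, mu, 1), 6)
    }
  }

  rows <- rows[sample.int(n), , drop = FALSE]
  rownames(rows) <- NULL
  attr(rows, "annotated_features") <- schema$name
  ds <- mutation_dataset(proteins, rows)
  truth <- list(
    informative_channels = if (eff > 0) ch else character(0),
    effect_size = eff,
    af_features = if (af_on) c(PLANTED_AF_BINARY, PLANTED_AF_NUMERIC) else character(0),
    substitution_property = if (sub_on) "KYTJ820101" else NULL,
    pss_bias = if (pss_on) "within-group dipeptide enrichment in driver-pool proteins" else NULL,
    seed = cfg$seed)
  list(dataset = ds, truth = truth)
}

#' Simulate a plain tabular feature matrix (fast mode)
#'
#' Direct tabular generator for selection/classifier unit tests: a balanced
#' two-class Gaussian design where the first `n_informative` features have
#' driver means shifted by `effect_size` (in sigma units) and the rest are
#' pure noise. Bypasses the encoders deliberately.
#'
#' @param n_per_class Samples per class.
#' @param n_features Total features.
#' @param n_informative Number of class-informative features (the first
#'   columns).
#' @param effect_size Mean shift of informative features, in sigma.
#' @param seed RNG seed.
#' @return List: `x` (matrix with rownames/colnames), `labels` (factor),
#'   `informative` (character vector of planted feature names).
#' @export
simulate_feature_matrix <- function(n_per_class = 100, n_features = 20,
                                    n_informative = 5, effect_size = 2,
                                    seed = 1) {
  if (n_informative > n_features) stop_config("n_informative > n_features")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- 2L * n_per_class
  labels <- factor(rep(c("driver", "passenger"), each = n_per_class),
                   levels = c("driver", "passenger"))
  x <- matrix(rnorm(n * n_features), n, n_features,
              dimnames = list(sprintf("s%04d", seq_len(n)),
                              sprintf("f%03d", seq_len(n_features))))
  if (n_informative > 0) {
    x[labels == "driver", seq_len(n_informative)] <-
      x[labels == "driver", seq_len(n_informative)] + effect_size
  }
  perm <- sample.int(n)
  list(x = x[perm, , drop = FALSE], labels = labels[perm],
       informative = colnames(x)[seq_len(n_informative)])
}

#' Write a simulated dataset as a reusable fixture
#'
#' Emits the exact formats the core readers consume: `sequences.fasta`,
#' `mutations.tsv` and `ground_truth.json` inside `dir`.
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if absent).
#' @param force Overwrite a non-empty directory (default `FALSE`).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !force) {
    stop_validation(sprintf("directory '%s' is not empty (use force = TRUE)", dir))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- sim$dataset
  write_fasta(ds$proteins, file.path(dir, "sequences.fasta"))
  m <- ds$mutations
  attr(m, "annotated_features") <- ds$annotated
  write_mutations(m, file.path(dir, "mutations.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a fixture directory back into a dataset
#'
#' @param dir Directory written by [write_fixture()].
#' @return List with `dataset` and `truth` (NULL if no ground-truth file).
#' @export
read_fixture <- function(dir) {
  proteins <- read_fasta(file.path(dir, "sequences.fasta"))
  mutations <- read_mutations(file.path(dir, "mutations.tsv"))
  truth_path <- file.path(dir, "ground_truth.json")
  truth <- if (file.exists(truth_path)) jsonlite::read_json(truth_path, simplifyVector = TRUE) else NULL
  list(dataset = mutation_dataset(proteins, mutations), truth = truth)
}
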