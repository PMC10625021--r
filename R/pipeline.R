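#' Configuration for an end-to-end pipeline run
#'
#' @param out_dir directory all stage outputs are written into.
#' @param n_patients cohort size for the simulate stage.
#' @param rng_seed root seed for the whole run.
#' @param k_medoids compression target K.
#' @param n_clusters cut count C.
#' @param window_days observation window T.
#' @param events_file,covariates_file paths to user-supplied input tables;
#'   when both are given the simulate stage is skipped.
#' @param generator a [generator_config()] overriding the default
#'   simulate-stage parameters (its n_patients and rng_seed are replaced
#'   by the run-level values).
#' @param rules a [selection_rules()] object.
#' @return a \code{run_config} list.
#' @export
run_config <- function(out_dir, n_patients = 2000L, rng_seed = 1L,
                       k_medoids = 100L, n_clusters = 4L,
                       window_days = 365L,
                       events_file = NULL, covariates_file = NULL,
                       generator = NULL, rules = selection_rules()) {
  structure(list(out_dir = out_dir, n_patients = as.integer(n_patients),
                 rng_seed = as.integer(rng_seed),
                 k_medoids = as.integer(k_medoids),
                 n_clusters = as.integer(n_clusters),
                 window_days = as.integer(window_days),
                 events_file = events_file,
                 covariates_file = covariates_file,
                 generator = generator, rules = rules),
            class = "run_config")
}

config_hash <- function(cfg) {
  txt <- paste(deparse(cfg[setdiff(names(cfg), "out_dir")]), collapse = "")
  b <- utf8ToInt(txt)
  sprintf("%08x", sum(b * (seq_along(b) %% 97 + 1)) %% 4294967296)
}

default_profile_specs <- function() {
  list(
    profile_spec("age", "continuous"),
    profile_spec("sex", "categorical"),
    profile_spec("undernutrition", "categorical"),
    profile_spec("morbid_obesity", "categorical"),
    profile_spec("diabetes", "categorical"),
    profile_spec("exacerbation_hospitalisations", "categorical",
                 source = "event:copd_exacerbation_stay",
                 breaks = c(-1, 0, 2, 4, Inf),
                 labels = c("0", "1-2", "3-4", ">=5")),
    profile_spec("gp_consultations", "categorical",
                 source = "event:gp_consult",
                 breaks = c(-1, 0, 2, 5, 10, 20, Inf),
                 labels = c("0", "1-2", "3-5", "6-10", "11-20", ">20")))
}

#' Run the full trajectory-clustering pipeline
#'
#' simulate (or load) -> select -> encode -> compress -> cluster ->
#' profile -> survive, writing every stage artifact as delimited text under
#' \code{config$out_dir} together with a JSON manifest (seed, config hash,
#' per-stage row counts and timings).  Reruns with the same config
#' reproduce identical numeric outputs.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly (also written to
#'   \code{out_dir/manifest.json}).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  tick <- function(name, rows, t0) {
    stages[[length(stages) + 1L]] <<- list(
      stage = name, rows = rows,
      seconds = round(as.numeric(Sys.time()) - t0, 3))
  }
  out <- function(f) file.path(config$out_dir, f)

  # 1. simulate (or load user tables)
  t0 <- as.numeric(Sys.time())
  if (!is.null(config$events_file) && !is.null(config$covariates_file)) {
    events <- read_stage_table(config$events_file)
    covariates <- read_stage_table(config$covariates_file)
    truth <- NULL
  } else {
    gen <- if (is.null(config$generator)) generator_config() else
      config$generator
    gen$n_patients <- config$n_patients
    gen$rng_seed <- config$rng_seed
    gen$window_days <- config$window_days
    cohort <- generate_cohort(gen)
    events <- cohort$events; covariates <- cohort$covariates
    truth <- cohort$truth
    write_stage_table(truth, out("truth.tsv"))
  }
  write_stage_table(events, out("events.tsv"))
  write_stage_table(covariates, out("covariates.tsv"))
  tick("simulate", nrow(events), t0)

  # 2. select
  t0 <- as.numeric(Sys.time())
  sel <- select_cohort(events, covariates, config$rules)
  write_stage_table(data.frame(reason = names(sel$attrition),
                               n = as.integer(sel$attrition)),
                    out("attrition.tsv"))
  covariates <- covariates[covariates$patient_id %in% sel$included, ]
  events <- events[events$patient_id %in% sel$included, ]
  tick("select", length(sel$included), t0)

  # 3. encode
  t0 <- as.numeric(Sys.time())
  alphabet <- state_alphabet()
  seqs <- encode_cohort(events, covariates$patient_id, alphabet,
                        config$window_days)
  write_sequences(seqs, out("sequences.tsv"))
  tick("encode", nrow(seqs), t0)

  # 4. compress
  t0 <- as.numeric(Sys.time())
  ms <- compress_sequences(seqs, config$k_medoids,
                           rng_seed = config$rng_seed)
  write_stage_table(data.frame(patient_id = rownames(seqs),
                               medoid = ms$assignment,
                               homogeneity = ms$homogeneity),
                    out("assignment.tsv"))
  mseq <- ms$medoids
  rownames(mseq) <- sprintf("m%04d", seq_len(ms$k))
  write_sequences(mseq, out("medoids.tsv"))
  tick("compress", ms$k, t0)

  # 5. cluster
  t0 <- as.numeric(Sys.time())
  D <- hamming_matrix(ms$medoids)
  model <- ward_cluster(D, ms$member_counts, config$n_clusters)
  model <- order_by_severity(model, seqs, ms$assignment)
  pat_labels <- model$labels[ms$assignment]
  write_stage_table(data.frame(patient_id = rownames(seqs),
                               cluster = pat_labels),
                    out("labels.tsv"))
  write_stage_table(data.frame(medoid = rownames(mseq),
                               cluster = model$labels,
                               members = ms$member_counts),
                    out("medoid_clusters.tsv"))
  raster <- visualization_matrix(model, ms$medoids, ms$member_counts)
  rownames(raster) <- sprintf("r%06d", seq_len(nrow(raster)))
  write_sequences(raster, out("raster.tsv"))
  tick("cluster", config$n_clusters, t0)

  # 6. profile
  t0 <- as.numeric(Sys.time())
  prof <- profile_clusters(covariates, events, pat_labels,
                           default_profile_specs())
  write_stage_table(prof, out("profile.tsv"))
  tick("profile", nrow(prof), t0)

  # 7. survive
  t0 <- as.numeric(Sys.time())
  rec <- survival_records(covariates, pat_labels)
  km_tabs <- do.call(rbind, lapply(sort(unique(rec$cluster)), function(cc) {
    sub <- rec[rec$cluster == cc, ]
    cbind(cluster = cc, as.data.frame(km_fit(sub$time, sub$event)))
  }))
  write_stage_table(km_tabs, out("km.tsv"))
  lr <- log_rank(rec$time, rec$event, rec$cluster, pairwise = TRUE)
  write_stage_table(data.frame(statistic = lr$statistic, df = lr$df,
                               p_value = lr$p_value),
                    out("logrank_global.tsv"))
  write_stage_table(lr$pairwise, out("logrank_pairwise.tsv"))
  X <- stats::model.matrix(~ age + sex + charlson + cluster, rec)[, -1L]
  cox <- cox_fit(rec$time, rec$event, X)
  write_stage_table(cox$coefficients, out("cox.tsv"))
  tick("survive", nrow(rec), t0)

  manifest <- list(package = "trajcluster",
                   version = as.character(utils::packageVersion("trajcluster")),
                   rng_seed = config$rng_seed,
                   config_hash = config_hash(config),
                   n_patients = config$n_patients,
                   k_medoids = config$k_medoids,
                   n_clusters = config$n_clusters,
                   stages = stages)
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
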