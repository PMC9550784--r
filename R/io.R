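CHANNELS <- c("phospho", "total", "negative_control")

## Structural validation shared by the reader and the analysis entry points.
validate_phospho_dataset <- function(ds) {
  need <- c("molecule_id", "channel", "time_min", "replicate", "intensity",
            "condition")
  miss <- setdiff(need, names(ds))
  if (length(miss)) {
    stop("dataset is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!ds$channel %in% CHANNELS)
  if (length(bad)) {
    stop(sprintf("unknown channel '%s' at row %d (expected %s)",
                 ds$channel[bad[1]], bad[1], paste(CHANNELS, collapse = "/")),
         call. = FALSE)
  }
  nonpos <- which(!is.finite(ds$intensity) | ds$intensity <= 0)
  if (length(nonpos)) {
    stop(sprintf("nonpositive intensity at row %d (molecule %s, t = %g)",
                 nonpos[1], ds$molecule_id[nonpos[1]], ds$time_min[nonpos[1]]),
         call. = FALSE)
  }
  times <- sort(unique(ds$time_min))
  reps <- sort(unique(ds$replicate))
  nc <- ds[ds$channel == "negative_control", ]
  if (nrow(nc) == 0) stop("no negative_control records", call. = FALSE)
  have_nc <- tidyr::expand_grid(time_min = times, replicate = reps)
  got <- dplyr::semi_join(have_nc, nc, by = c("time_min", "replicate"))
  if (nrow(got) < nrow(have_nc)) {
    gap <- dplyr::anti_join(have_nc, nc, by = c("time_min", "replicate"))[1, ]
    stop(sprintf("negative_control missing at time %g, replicate %d",
                 gap$time_min, gap$replicate), call. = FALSE)
  }
  mol <- ds[ds$channel == "phospho", ]
  counts <- dplyr::count(mol, .data$molecule_id, .data$time_min)
  if (length(unique(counts$n)) > 1 || counts$n[1] != length(reps)) {
    off <- counts[counts$n != length(reps), ][1, ]
    stop(sprintf("incomplete replicates for molecule %s at time %g",
                 off$molecule_id, off$time_min), call. = FALSE)
  }
  invisible(ds)
}

#' Write a phospho-array dataset as tab-separated text
#'
#' @param dataset Long-format dataset tibble.
#' @param path Output file path (`.tsv`).
#' @return `path`, invisibly.
#' @export
write_phospho_dataset <- function(dataset, path) {
  readr::write_tsv(dataset, path)
  invisible(path)
}

#' Read a phospho-array dataset
#'
#' Reads the long tab- or comma-separated dialect written by
#' [write_phospho_dataset()] (columns `molecule_id`, `channel`, `time_min`,
#' `replicate`, `intensity`, `condition`), or — with `format = "wide"` — the
#' wide export common to array scanners: columns `molecule_id`, `channel`,
#' `replicate`, plus one column per measurement time (named `0, 15, ...` or
#' `t0, t15, ...`). The dataset is validated structurally: channel
#' vocabulary, positive intensities, complete replicates, and a
#' negative-control spot at every time point.
#'
#' @param path Input file; `.csv` is read as comma-separated, anything else
#'   as tab-separated.
#' @param format `"long"` (default) or `"wide"`.
#' @param condition Condition label to attach when the file has no
#'   `condition` column.
#' @return A validated long-format tibble.
#' @export
read_phospho_dataset <- function(path, format = c("long", "wide"),
                                 condition = "unknown") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  reader <- if (grepl("\\.csv$", path)) readr::read_csv else readr::read_tsv
  raw <- reader(path, show_col_types = FALSE, progress = FALSE)
  if (format == "wide") {
    id_cols <- c("molecule_id", "channel", "replicate")
    miss <- setdiff(id_cols, names(raw))
    if (length(miss)) {
      stop("wide file is missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    time_cols <- setdiff(names(raw), c(id_cols, "condition"))
    tvals <- suppressWarnings(as.numeric(sub("^[tX]", "", time_cols)))
    if (anyNA(tvals)) {
      stop("wide file has non-time column(s): ",
           paste(time_cols[is.na(tvals)], collapse = ", "), call. = FALSE)
    }
    raw <- tidyr::pivot_longer(raw, dplyr::all_of(time_cols),
                               names_to = "time_min", values_to = "intensity")
    raw$time_min <- as.numeric(sub("^[tX]", "", raw$time_min))
  }
  if (!"condition" %in% names(raw)) raw$condition <- condition
  raw$replicate <- as.integer(raw$replicate)
  out <- tibble::as_tibble(raw)[, c("molecule_id", "channel", "time_min",
                                    "replicate", "intensity", "condition")]
  validate_phospho_dataset(out)
  out
}

#' Write simulated data and its ground truth
#'
#' Writes the dataset of a [dataset_spec()] as `dataset.tsv` plus a
#' `ground_truth.json` sidecar with the true durations and STRs.
#'
#' @param spec A [dataset_spec()].
#' @param out_dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
simulate_to_dir <- function(spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_phospho_dataset(generate_dataset(spec), file.path(out_dir, "dataset.tsv"))
  jsonlite::write_json(ground_truth(spec), file.path(out_dir, "ground_truth.json"),
                       dataframe = "rows", digits = NA, na = "null")
  invisible(out_dir)
}

#' Reported cascade-step similarity statistics
#'
#' Reference posterior statistics for the steps of the proliferative
#' Src-Raf1-MEK1-ERK1 (SRME) and stress-responsive ASK1-MKK4/MKK3-JNK
#' (AMMJ) cascades in EGF-stimulated A431 cells, with and without
#' starvation stress, bundled for regression-testing the similarity
#' verdict: EAP STR difference, effect size, probability of dominance and
#' direction probability at the one-decimal precision at which they were
#' reported, together with the reported per-criterion and overall
#' similarity calls.
#'
#' @return Tibble with columns `condition`, `cascade`, `step_a`, `step_b`,
#'   `str_diff`, `effect_size`, `pi_d`, `d_pi`, `c1_reported`,
#'   `c2_reported`, `c3_reported`, `similar_reported`.
#' @export
cascade_step_statistics <- function() {
  path <- system.file("extdata", "a431_step_statistics.tsv", package = "sigstr",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

derive_seed <- function(master, salt) {
  as.integer((as.numeric(master) * 48271 + salt) %% 2147483647)
}

#' Default cascade declarations
#'
#' The two canonical EGF-related cascades: proliferative SRME
#' (Src-Raf1-MEK1-ERK1) and stress-responsive AMMJ (ASK1-MKK4/MKK3-JNK,
#' with the branched second step).
#'
#' @return Named list of [cascade_spec()] objects.
#' @export
default_cascades <- function() {
  list(SRME = cascade_spec("SRME", c("Src", "Raf1", "MEK1", "ERK1")),
       AMMJ = cascade_spec("AMMJ", c("ASK1", "MKK4|MKK3", "JNK")))
}

#' Configure an end-to-end pipeline run
#'
#' @param dataset A long-format dataset tibble, or `NULL`.
#' @param spec A [dataset_spec()] to simulate from when `dataset` is `NULL`.
#' @param input_path Path to a dataset file when neither `dataset` nor
#'   `spec` is given.
#' @param input_format Dialect for `input_path` (see
#'   [read_phospho_dataset()]).
#' @param signal_threshold Detection threshold on the excess ratio used for
#'   molecule duration estimation. The default 0.3 (fold-change 1.3) is
#'   about twice the log-scale noise SD of the normalized ratio at the
#'   nominal replicate CV of 0.08, suppressing noise-driven duration
#'   estimates.
#' @param mcmc An [mcmc_config()]; its seed is re-derived per molecule from
#'   the master `seed`.
#' @param delta_max,band Similarity thresholds (see [similarity_verdict()]).
#' @param cascades Named list of [cascade_spec()] objects to call.
#' @param candidate_edges Optional two-column matrix/data frame of extra
#'   molecule pairs to assess (hypothesis-generation edges downstream of the
#'   declared cascades).
#' @param fallback_floor Noise floor (1/min) used when the dataset carries
#'   no negative-control STRs; default 0.10.
#' @param floor_override Optional fixed noise floor (1/min) that bypasses
#'   the negative-control computation entirely.
#' @param perplexity,tsne_iter Embedding parameters.
#' @param seed Master seed; every stochastic stage derives its own seed
#'   from it.
#' @param out_dir Optional output directory for the TSV/JSON artifacts.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(dataset = NULL, spec = NULL, input_path = NULL,
                            input_format = "long",
                            signal_threshold = 0.3, mcmc = mcmc_config(),
                            delta_max = 0.3, band = c(0.4, 0.6),
                            cascades = default_cascades(),
                            candidate_edges = NULL,
                            fallback_floor = 0.10, floor_override = NULL,
                            perplexity = 5, tsne_iter = 1000,
                            seed = 1L, out_dir = NULL) {
  if (is.null(dataset) && is.null(spec) && is.null(input_path)) {
    stop("provide one of `dataset`, `spec` or `input_path`", call. = FALSE)
  }
  stopifnot(signal_threshold >= 0, inherits(mcmc, "mcmc_config"),
            delta_max > 0, length(band) == 2, band[1] < band[2],
            fallback_floor >= 0, perplexity > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full STR analysis pipeline
#'
#' Chains every stage: data ingestion (or simulation), ratio normalization,
#' per-replicate duration and STR estimation, the negative-control noise
#' floor, outlier trimming and Bayesian posterior fits per molecule,
#' pairwise similarity assessment of all cascade and candidate edges,
#' cascade activation calls, and the 2-D embedding of trimmed replicate STR
#' vectors. All randomness derives from the master seed, so a repeated run
#' with the same configuration reproduces the report exactly.
#'
#' When `out_dir` is set, writes `str.tsv`, `similarity.tsv`,
#' `cascades.json`, `embedding.tsv` and `report.json`.
#'
#' @param cfg A [pipeline_config()].
#' @return A list of class `"pipeline_report"`: the configuration snapshot,
#'   STR table, posterior summaries, similarity assessments, cascade calls,
#'   noise floor and embedding coordinates.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dataset <- cfg$dataset
  if (is.null(dataset) && !is.null(cfg$spec)) dataset <- generate_dataset(cfg$spec)
  if (is.null(dataset)) {
    dataset <- read_phospho_dataset(cfg$input_path, format = cfg$input_format)
  }
  validate_phospho_dataset(dataset)

  ratios <- normalize_ratios(dataset)
  strs <- str_table(ratios, signal_threshold = cfg$signal_threshold)

  ## noise floor: negative-control spots through the same estimators, at
  ## zero detection threshold so the floor reflects the largest STR that
  ## noise alone produces
  floor <- if (!is.null(cfg$floor_override)) {
    cfg$floor_override
  } else {
    nc_ratios <- negative_control_ratios(dataset)
    nc_strs <- str_table(nc_ratios, signal_threshold = 0)
    if (nrow(nc_strs) > 0) {
      noise_floor(ifelse(nc_strs$status == "no_signal", NA_real_, nc_strs$beta))
    } else {
      cfg$fallback_floor
    }
  }

  molecules <- setdiff(unique(strs$molecule_id), "negative_control")
  posteriors <- stats::setNames(purrr::map(seq_along(molecules), function(i) {
    b <- strs$beta[strs$molecule_id == molecules[i]]
    b <- b[is.finite(b)]
    kept <- trim_outliers(b)
    fit_cfg <- cfg$mcmc
    fit_cfg$seed <- derive_seed(cfg$seed, i)
    fit_posterior(kept, fit_cfg, molecule_id = molecules[i])
  }), molecules)

  edges <- dplyr::bind_rows(purrr::map(cfg$cascades, ~ .x$edges))
  if (!is.null(cfg$candidate_edges)) {
    ce <- as.data.frame(cfg$candidate_edges)
    names(ce) <- c("from", "to")
    edges <- dplyr::bind_rows(edges, ce)
  }
  edges <- dplyr::distinct(edges)
  missing <- setdiff(unique(c(edges$from, edges$to)), molecules)
  if (length(missing)) {
    stop("cascade molecule(s) absent from dataset: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  assessments <- dplyr::bind_rows(purrr::map(seq_len(nrow(edges)), function(i) {
    assess_pair(posteriors[[edges$from[i]]], posteriors[[edges$to[i]]],
                seed = derive_seed(cfg$seed, 10000 + i),
                delta_max = cfg$delta_max, band = cfg$band)
  }))

  calls <- purrr::map(cfg$cascades, assess_cascade, posteriors = posteriors,
                      assessments = assessments, floor = floor)

  vecs <- purrr::map(molecules, function(m) {
    b <- strs$beta[strs$molecule_id == m]
    b[!is.finite(b)] <- 0
    trim_minmax(b)
  })
  names(vecs) <- molecules
  coords <- embed_str_vectors(vecs, perplexity = min(cfg$perplexity,
                                                     length(vecs) - 1),
                              n_iter = cfg$tsne_iter,
                              seed = derive_seed(cfg$seed, 777))

  report <- structure(
    list(
      seed = cfg$seed,
      parameters = list(signal_threshold = cfg$signal_threshold,
                        delta_max = cfg$delta_max, band = cfg$band,
                        mcmc = unclass(cfg$mcmc),
                        perplexity = cfg$perplexity),
      condition = dataset$condition[1],
      noise_floor = floor,
      str = strs,
      posteriors = posteriors,
      similarity = assessments,
      cascade_calls = calls,
      embedding = coords
    ),
    class = "pipeline_report"
  )
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> condition '", x$condition, "', seed ", x$seed,
      ", noise floor ", signif(x$noise_floor, 3), "/min\n", sep = "")
  for (cc in x$cascade_calls) print(cc)
  invisible(x)
}

## serialize a pipeline report; every output is plain text
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$str, file.path(out_dir, "str.tsv"))
  readr::write_tsv(report$similarity, file.path(out_dir, "similarity.tsv"))
  readr::write_tsv(report$embedding, file.path(out_dir, "embedding.tsv"))
  post <- purrr::map(report$posteriors, function(p) {
    p[c("molecule_id", "eap_mu", "post_sd", "r_hat", "n_used", "converged")]
  })
  calls <- purrr::map(report$cascade_calls, unclass)
  jsonlite::write_json(calls, file.path(out_dir, "cascades.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(seed = report$seed, condition = report$condition,
         parameters = report$parameters, noise_floor = report$noise_floor,
         posteriors = post, cascade_calls = calls),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(out_dir)
}
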