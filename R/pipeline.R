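#' Run the full connectivity pipeline from a configuration
#'
#' Orchestrates simulation or file input, per-band preprocessing, similarity
#' computation, network construction, metrics, and pairwise network
#' comparison, writing all outputs (CSV matrices and edge lists, JSON
#' metrics and reports, a manifest with file checksums) under an output
#' directory. Every product is a deterministic function of the
#' configuration and its seed.
#'
#' The configuration is a YAML file or an R list with blocks:
#' \describe{
#'   \item{simulate}{arguments for [islet_sim_config()]; mutually exclusive
#'     with `input`.}
#'   \item{input}{`traces_csv`, optional `coords_csv`, `fs`, optional
#'     `intervals` path and `interval` name to analyze.}
#'   \item{bands}{character vector of band names (see [filter_spec()]);
#'     default `"fast"`.}
#'   \item{binarize}{`on_frac`, `off_frac`, `min_duration` for
#'     [binarize()].}
#'   \item{similarity}{methods among `correlation`, `coactivity`,
#'     `mutual_information`; default `correlation`.}
#'   \item{construct}{`methods` among `fixed_threshold`, `fixed_kavg`,
#'     `multilayer_mst`, `geometric`, plus `sc_th`, `target_kavg`,
#'     `n_layers`.}
#'   \item{metrics}{`sw_randomizations`, `hub_fraction`.}
#'   \item{output_dir, seed}{output location and master seed.}
#' }
#'
#' @param config YAML path or list.
#' @return Invisibly, a list with `networks` (named list of
#'   [functional_network()]s), `metrics` (named list), `nsi` (pairwise NSI
#'   matrix), `manifest`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  out_dir <- cfg$output_dir %||% stop("config needs `output_dir`",
                                      call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed %||% 1L
  bands <- cfg$bands %||% "fast"
  sim_methods <- cfg$similarity %||% "correlation"
  con <- cfg$construct %||% list()
  con_methods <- con$methods %||% "fixed_kavg"
  target_kavg <- con$target_kavg %||% 8
  n_layers <- con$n_layers %||% 4
  sc_th <- con$sc_th %||% 0.75
  met <- cfg$metrics %||% list()
  sw_rand <- met$sw_randomizations %||% 20
  bin_par <- cfg$binarize %||% list()

  # --- input -----------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim_args$seed <- sim_args$seed %||% seed
    islet <- generate_islet(do.call(islet_sim_config, sim_args))
    rec <- islet$recording
  } else if (!is.null(cfg$input)) {
    inp <- cfg$input
    rec <- read_recording_csv(inp$traces_csv, fs = inp$fs,
                              coords_csv = inp$coords_csv,
                              intervals = inp$intervals)
    if (!is.null(inp$interval)) rec <- subset_interval(rec, inp$interval)
    islet <- NULL
  } else stop("config needs a `simulate` or `input` block", call. = FALSE)

  networks <- list()
  metrics <- list()
  # --- per band x similarity x construction ----------------------------
  for (band in bands) {
    spec <- filter_spec(band)
    frec <- bandpass_filter(rec, spec)
    bin <- NULL
    for (sm in sim_methods) {
      S <- switch(
        sm,
        correlation = pearson_matrix(frec),
        coactivity = {
          if (is.null(bin))
            bin <- do.call(binarize, c(list(frec), bin_par))
          coactivity_matrix(bin)
        },
        mutual_information = {
          if (is.null(bin))
            bin <- do.call(binarize, c(list(frec), bin_par))
          nmi_matrix(bin)
        },
        stop(sprintf("unknown similarity method '%s'", sm), call. = FALSE)
      )
      write_similarity_csv(S, file.path(out_dir,
                                        sprintf("similarity_%s_%s.csv",
                                                band, sm)))
      for (cm in con_methods) {
        net <- switch(
          cm,
          fixed_threshold = fixed_threshold_network(S, sc_th, rec$coords),
          fixed_kavg = fixed_kavg_network(S, target_kavg,
                                          coords = rec$coords),
          multilayer_mst = multilayer_mst_network(S, n_layers, rec$coords),
          geometric = geometric_network(rec$coords, "target_kavg",
                                        target_kavg, rec$cell_ids),
          stop(sprintf("unknown construction method '%s'", cm),
               call. = FALSE)
        )
        key <- sprintf("%s_%s_%s", band, sm, cm)
        networks[[key]] <- net
        write_edges_csv(net, file.path(out_dir,
                                       sprintf("edges_%s.csv", key)))
        mm <- compute_metrics(net, sw_randomizations = sw_rand, seed = seed)
        metrics[[key]] <- mm
        jsonlite::write_json(
          list(network = key, seed = seed,
               k_avg = mm$k_avg, C_avg = mm$C_avg, Q = mm$Q, E = mm$E,
               L_avg = mm$L_avg, S_max = mm$S_max, SW = mm$SW),
          file.path(out_dir, sprintf("metrics_%s.json", key)),
          auto_unbox = TRUE, digits = NA, na = "null")
      }
    }
  }
  nsi_mat <- NULL
  if (length(networks) >= 2) {
    nsi_mat <- nsi_matrix(networks)
    utils::write.csv(nsi_mat, file.path(out_dir, "nsi_matrix.csv"))
  }
  # --- manifest --------------------------------------------------------
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  # config.yaml embeds the output path, so it is fingerprinted separately
  files <- sort(setdiff(list.files(out_dir),
                        c("manifest.json", "config.yaml")))
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(
    package_version = as.character(utils::packageVersion("isletnet")),
    seed = seed,
    config_md5 = unname(tools::md5sum(file.path(out_dir, "config.yaml"))),
    files = stats::setNames(as.list(unname(sums)), files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(networks = networks, metrics = metrics, nsi = nsi_mat,
                 manifest = manifest))
}
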