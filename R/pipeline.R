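#' Run the full pipeline on a table and write all artifacts
#'
#' Executes read -> ranking (six subsets) -> six phylogram models ->
#' clade/target sensitivity -> optional resampling suite -> forward-AIC Cox
#' model per feature list -> AIC normalization -> Pareto front and elbow,
#' writing every artifact plus a run manifest (config snapshot, input and
#' output content hashes) to the output directory. Reruns on identical
#' inputs produce identical hashes.
#'
#' @param input Path to a CSV file, or an `fsopa_table`.
#' @param config A [role_config()]; required when `input` is a path and
#'   used as-is when the table carries none.
#' @param out_dir Output directory (created).
#' @param targets SM2 targets; default the criterion column.
#' @param compressor Compressor name.
#' @param resample Run the RS1-RS6 resampling suite (default TRUE).
#' @param cox Fit forward-AIC Cox models (default TRUE; requires duration
#'   and event columns in the config).
#' @param min_subset Passed to [ss_sample()].
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(input, config = NULL, out_dir, targets = NULL,
                         compressor = "gzip", resample = TRUE, cox = TRUE,
                         min_subset = 10) {
  manifest <- list(tool = "fsopa", version = as.character(
    utils::packageVersion("fsopa")), compressor = compressor)
  if (inherits(input, "fsopa_table")) {
    table <- input
    if (!is.null(config)) table <- feature_table(table$data, config = config)
  } else {
    if (is.null(config)) stop("config required when reading from file")
    manifest$input <- list(path = input,
                           md5 = unname(tools::md5sum(input)))
    table <- read_feature_table(input, config = config)
  }
  cfg <- table$config
  if (is.null(cfg)) stop("a criterion configuration is required")
  if (cox && (is.null(cfg$event) ||
              (is.null(cfg$duration) && is.null(cfg$criterion))))
    stop("config error: Cox stage requires duration and event columns")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest$config <- cfg[c("criterion", "direction", "duration", "event",
                           "sentinels")]
  manifest$n <- table$n
  manifest$columns <- feature_names(table)

  ss <- ss_sample(table, min_subset = min_subset)
  sel <- select_features(table, ss, targets = targets,
                         compressor = compressor)
  outputs <- character(0)
  for (lab in subset_labels()) {
    p <- file.path(out_dir, paste0(lab, ".nwk"))
    write_newick(sel$models[[lab]], p)
    outputs <- c(outputs, p)
  }
  p <- file.path(out_dir, "selection.json")
  write_selection(sel, p)
  outputs <- c(outputs, p)

  lists <- list(full = sel$r)
  suite <- NULL
  if (resample) {
    suite <- run_resampling_suite(table, targets = targets,
                                  compressor = compressor,
                                  min_subset = min_subset)
    lists <- c(lists, list(rs1 = suite$selections$rs1$r,
                           rs2 = suite$selections$rs2$r,
                           rs3 = suite$selections$rs3$r,
                           rs4 = suite$rs4, rs5 = suite$rs5,
                           rs6 = suite$rs6))
    p <- file.path(out_dir, "suite_membership.csv")
    utils::write.csv(suite_membership(suite), p, row.names = FALSE)
    outputs <- c(outputs, p)
  }
  manifest$feature_lists <- lists

  if (cox) {
    spec <- cox_spec(table)
    drop <- c(spec$duration, spec$event, cfg$criterion)
    models <- list()
    for (nm in names(lists)) {
      cands <- setdiff(lists[[nm]], drop)
      models[[nm]] <- if (length(cands) == 0L)
        cox_fit(spec, character(0), label = nm)
      else forward_aic(spec, cands, label = nm)
    }
    models <- normalize_aic(models)
    tab <- model_table(models)
    p <- file.path(out_dir, "models.csv")
    utils::write.csv(tab, p, row.names = FALSE)
    outputs <- c(outputs, p)
    front <- pareto_front(models)
    p <- file.path(out_dir, "front.json")
    write_front(front, p)
    outputs <- c(outputs, p)
    el <- elbow(front)
    manifest$models <- tab
    manifest$elbow <- front$points$label[as.integer(el)]
  }
  manifest$outputs <- lapply(outputs, function(p)
    list(path = basename(p), md5 = unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, dataframe = "rows", digits = NA)
  invisible(manifest)
}
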