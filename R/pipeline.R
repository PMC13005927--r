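#' Default run configuration
#'
#' Centralizes every tunable of the detect - embed - align - map -
#' validate pipeline so the stages cannot drift apart. Values can be
#' overridden by a YAML file ([read_run_config()]) or by supplying
#' replacements.
#'
#' @param ... Named overrides of the defaults.
#' @return A `run_config` list with elements: `paths` (events_a, covars_a,
#'   events_b, covars_b, groups), `min_freq` (non-rare threshold, 10),
#'   `embed` (`window` 30 days, `d` 20, `mode` "PMI", `shift` 1), `align`
#'   (`method` "rotation", `lambda` 0.1), `map` (`similarity` "DS",
#'   `refine_gamma` 0 = off, `selection` "top1", `K`, `folds` 5), `validate`
#'   (`folds` 5, `transform` "log1p", `lambda` 1), `seed`.
#' @export
run_config <- function(...) {
  cfg <- list(
    paths = list(events_a = NULL, covars_a = NULL, events_b = NULL,
                 covars_b = NULL, groups = NULL),
    min_freq = 10L,
    embed = list(window = 30L, d = 20L, mode = "PMI", shift = 1),
    align = list(method = "rotation", lambda = 0.1),
    map = list(similarity = "DS", refine_gamma = 0, selection = "top1",
               K = 1L, folds = 5L),
    validate = list(folds = 5L, transform = "log1p", lambda = 1),
    seed = 1L)
  ov <- list(...)
  for (nm in names(ov)) {
    if (is.list(cfg[[nm]]) && is.list(ov[[nm]]))
      cfg[[nm]][names(ov[[nm]])] <- ov[[nm]]
    else cfg[[nm]] <- ov[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#' @param path YAML file with (a subset of) the [run_config()] fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

stage_log <- function(stage, t0) {
  message(sprintf("[codeharmony] %-10s %.2fs", stage,
                  as.numeric(Sys.time()) - t0))
}

#' Write a synthetic scenario as pipeline-ready fixtures
#'
#' Generates one of the built-in scenarios and writes the standard CSV
#' inputs (`events_a.csv`, `covars_a.csv`, `events_b.csv`,
#' `covars_b.csv`, `groups.csv`) plus `ground_truth.json` to a directory.
#' Byte-identical across runs with the same scenario and seed.
#'
#' @param scenario One of `"null"`, `"substitution"`, `"granularity"`.
#' @param dir Output directory (created if needed).
#' @param n_patients Patients per site.
#' @param seed Integer seed.
#' @return The directory path, invisibly.
#' @export
run_synthesize <- function(scenario, dir, n_patients = 1000L, seed = 1L) {
  maker <- switch(scenario,
                  null = scenario_null,
                  substitution = scenario_substitution,
                  granularity = scenario_granularity,
                  stop("unknown scenario '", scenario,
                       "'; options: null, substitution, granularity"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  config <- maker(n_patients = n_patients, seed = seed)
  coh <- generate_cohort(config)
  write_events(coh$events_a, file.path(dir, "events_a.csv"))
  write_covariates(coh$covars_a, file.path(dir, "covars_a.csv"))
  write_events(coh$events_b, file.path(dir, "events_b.csv"))
  write_covariates(coh$covars_b, file.path(dir, "covars_b.csv"))
  cat_tbl <- synth_group_catalog(config)
  fwrite(data.table(code = names(cat_tbl$code2group),
                    group_id = unname(cat_tbl$code2group)),
         file.path(dir, "groups.csv"))
  tr <- coh$truth
  jsonlite::write_json(
    list(map = lapply(tr$map, function(m) m),
         planted_codes = tr$planted_codes,
         planted_groups = tr$planted_groups,
         null_groups = tr$null_groups),
    file.path(dir, "ground_truth.json"), auto_unbox = FALSE, digits = NA)
  invisible(dir)
}

#' Run the full harmonization pipeline
#'
#' Executes detection, embedding, alignment, mapping and validation in
#' order on the configured inputs and writes all artifacts plus a run
#' manifest (seed, settings, artifact checksums) to `out_dir`. Idempotent
#' given the seed. Stage errors abort with the stage name.
#'
#' @param config A [run_config()] whose `paths` point at the input CSVs.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the detection report, similarity,
#'   mapping spec, harmonizer, and validation reports.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- as.numeric(Sys.time())
  run_stage <- function(stage, expr) {
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    stage_log(stage, t0)
    out
  }

  inp <- run_stage("read", {
    p <- config$paths
    for (nm in names(p))
      if (is.null(p[[nm]]) || !file.exists(p[[nm]]))
        stop("input path '", nm, "' missing or not found")
    list(events_a = read_events(p$events_a, "A"),
         covars_a = read_covariates(p$covars_a),
         events_b = read_events(p$events_b, "B"),
         covars_b = read_covariates(p$covars_b),
         groups = read_code_groups(p$groups))
  })

  det <- run_stage("detect", {
    detect_report(inp$events_a, inp$covars_a, inp$events_b, inp$covars_b,
                  inp$groups)
  })
  fwrite(det, file.path(out_dir, "report.csv"))

  emb <- run_stage("embed", {
    fa <- summarize_frequencies(inp$events_a, inp$covars_a)
    fb <- summarize_frequencies(inp$events_b, inp$covars_b)
    va <- nonrare_vocab(fa, config$min_freq)
    vb <- nonrare_vocab(fb, config$min_freq)
    d <- min(config$embed$d, length(va), length(vb))
    ea <- embed_codes(pmi_matrix(count_cooccurrence(inp$events_a, va,
                                                    config$embed$window),
                                 config$embed$mode, config$embed$shift), d)
    eb <- embed_codes(pmi_matrix(count_cooccurrence(inp$events_b, vb,
                                                    config$embed$window),
                                 config$embed$mode, config$embed$shift), d)
    write_embeddings(ea, file.path(out_dir, "embeddings_a.csv"))
    write_embeddings(eb, file.path(out_dir, "embeddings_b.csv"))
    list(ea = ea, eb = eb, fa = fa, fb = fb)
  })

  ali <- run_stage("align", {
    map <- if (config$align$method == "rotation")
      rotation_align(emb$ea, emb$eb)
    else projection_align(emb$ea, emb$eb, lambda = config$align$lambda)
    fwrite(as.data.table(map$T), file.path(out_dir, "alignment.csv"))
    jsonlite::write_json(list(method = map$method, lambda = map$lambda,
                              objective = map$objective,
                              n_anchors = map$n_anchors),
                         file.path(out_dir, "alignment.json"),
                         auto_unbox = TRUE, digits = NA)
    align_embeddings(emb$ea, map)
  })

  mp <- run_stage("map", {
    sim <- if (config$map$similarity == "RS")
      regression_similarity(ali, emb$eb, inp$groups,
                            lambda = config$align$lambda)
    else directional_similarity(ali, emb$eb, inp$groups)
    if (config$map$refine_gamma > 0)
      sim <- frequency_refine(sim, emb$fa, emb$fb,
                              gamma = config$map$refine_gamma)
    ref_freq <- setNames(emb$fb$frequency, emb$fb$code)
    vocab_a <- sim$source_vocab
    Xa_cnt <- patient_code_matrix(inp$events_a, inp$covars_a, vocab_a, "count")
    Xb_cnt <- patient_code_matrix(inp$events_b, inp$covars_b, sim$ref_vocab,
                                  "count")
    spec <- switch(config$map$selection,
                   top1 = select_topk(sim, 1L, ref_freq),
                   top2 = select_topk(sim, 2L, ref_freq),
                   threshold = select_threshold_cv(sim, Xa_cnt, Xb_cnt,
                                                   folds = config$map$folds,
                                                   seed = config$seed,
                                                   ref_freq = ref_freq)$spec,
                   stop("unknown selection rule: ", config$map$selection))
    H <- build_harmonizer(spec, sim)
    write_mapping(spec, file.path(out_dir, "mapping.csv"))
    trip <- which(H$M != 0, arr.ind = TRUE)
    fwrite(data.table(source_code = rownames(H$M)[trip[, 1L]],
                      reference_code = colnames(H$M)[trip[, 2L]],
                      weight = H$M[trip]),
           file.path(out_dir, "operator.csv"))
    list(sim = sim, spec = spec, H = H, Xa = Xa_cnt, Xb = Xb_cnt)
  })

  val <- run_stage("validate", {
    Xh <- apply_harmonizer(mp$Xa, mp$H)
    # the classifier sees only codes inside the mapped clinical
    # categories: mapping cannot (and should not) confuse codes it was
    # never allowed to move, such as ungrouped site-local codes
    ref_scope <- mp$sim$ref_vocab[group_of(inp$groups, mp$sim$ref_vocab) !=
                                    "ungrouped"]
    src_scope <- mp$sim$source_vocab[group_of(inp$groups,
                                              mp$sim$source_vocab) !=
                                       "ungrouped"]
    after <- site_auc(mp$Xb[, ref_scope, drop = FALSE],
                      Xh[, ref_scope, drop = FALSE],
                      folds = config$validate$folds,
                      seed = config$seed,
                      transform = config$validate$transform,
                      lambda = config$validate$lambda)
    before <- baseline_overlap_auc(mp$Xb[, ref_scope, drop = FALSE],
                                   mp$Xa[, src_scope, drop = FALSE],
                                   folds = config$validate$folds,
                                   seed = config$seed,
                                   transform = config$validate$transform,
                                   lambda = config$validate$lambda)
    jsonlite::write_json(
      list(baseline = list(auc = before$auc, ci = unname(before$ci)),
           harmonized = list(auc = after$auc, ci = unname(after$ci)),
           folds = config$validate$folds, seed = config$seed),
      file.path(out_dir, "validation.json"), auto_unbox = TRUE, digits = NA)
    list(before = before, after = after)
  })

  arts <- list.files(out_dir, full.names = TRUE)
  arts <- arts[basename(arts) != "manifest.json"]
  manifest <- list(seed = config$seed,
                   settings = unclass(config)[setdiff(names(config), "paths")],
                   artifacts = as.list(setNames(unname(tools::md5sum(arts)),
                                                basename(arts))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(report = det, similarity = mp$sim, spec = mp$spec,
                 harmonizer = mp$H, validation = val))
}

#' Heterogeneity detection report for two sites
#'
#' Code-level weighted t-tests and smoothed frequency ratios over the
#' union vocabulary, and burden + SKAT tests per shared code group, with
#' Bonferroni adjustment within each family (codes and groups
#' separately).
#'
#' @param events_a,covars_a Site A (source) data.
#' @param events_b,covars_b Site B (reference) data.
#' @param groups A [group_catalog()].
#' @param min_freq Restrict code-level tests to codes with pooled
#'   frequency at least this (default 10).
#' @return `data.table(unit, kind, statistic, p, p_adj, ratio)`.
#' @export
detect_report <- function(events_a, covars_a, events_b, covars_b, groups,
                          min_freq = 10L) {
  fa <- summarize_frequencies(events_a, covars_a)
  fb <- summarize_frequencies(events_b, covars_b)
  rt <- frequency_ratio_table(fa, fb)
  rt <- rt[f_a + f_b >= min_freq]
  covars <- rbind(as.data.table(covars_a), as.data.table(covars_b))
  site <- c(rep(1, nrow(covars_a)), rep(0, nrow(covars_b)))
  vocab <- rt$code
  Xa <- patient_code_matrix(events_a, covars_a, vocab, "count")
  Xb <- patient_code_matrix(events_b, covars_b, vocab, "count")
  cnt <- rbind(as.matrix(Xa), as.matrix(Xb))
  rates <- cnt / covars$person_time
  Z <- cbind(age = covars$age, sex = covars$sex,
             insulin_use = covars$insulin_use, elixhauser = covars$elixhauser)
  code_res <- rbindlist(lapply(seq_along(vocab), function(j)
    code_level_test(rates[, j], site, Z, covars$person_time, unit = vocab[j])))
  code_res[, p_adj := bonferroni_adjust(p)]
  code_res[, ratio := rt$ratio[match(unit, rt$code)]]

  null <- fit_null_model(Z, site)
  shared_groups <- sort(unique(group_of(groups, vocab)))
  shared_groups <- setdiff(shared_groups, "ungrouped")
  grp_res <- rbindlist(lapply(shared_groups, function(g) {
    members <- intersect(groups$members[[g]], vocab)
    G <- cnt[, members, drop = FALSE]
    rbind(burden_test(null, G, unit = g), skat_test(null, G, unit = g),
          fill = TRUE)
  }), fill = TRUE)
  if (nrow(grp_res)) {
    grp_res[, p_adj := bonferroni_adjust(p, m = length(shared_groups)), by = kind]
    ga <- merge(data.table(group = group_of(groups, rt$code), f_a = rt$f_a,
                           f_b = rt$f_b),
                data.table(group = shared_groups), by = "group")
    gsum <- ga[, .(ratio = smoothed_frequency_ratio(sum(f_a), sum(f_b),
                                                    fa$person_time[1L],
                                                    fb$person_time[1L])$ratio),
               by = group]
    grp_res[, ratio := gsum$ratio[match(unit, gsum$group)]]
  }
  out <- rbind(code_res[, .(unit, kind, statistic, p, p_adj, ratio)],
               if (nrow(grp_res)) grp_res[, .(unit, kind, statistic, p, p_adj, ratio)])
  out[]
}
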