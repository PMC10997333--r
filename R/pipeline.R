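#' Default pipeline configuration
#'
#' A demo-scale configuration that runs the whole pipeline on one CPU in a
#' few minutes: 20 sentence sets (40 target sentences), a 50-vertex mesh,
#' 12 participants and 500 cluster permutations.
#'
#' @param outDir output directory.
#' @param seed master seed; every stage derives its randomness from it.
#' @return nested named list understood by [runPipeline()] /
#'   [validateConfig()].
#' @export
defaultConfig <- function(outDir = file.path(tempdir(), "incstruct-run"),
                          seed = 1L) {
  list(
    seed = as.integer(seed),
    out_dir = outDir,
    stages = c("generate", "probe", "measures", "geometry", "rsa",
               "cluster", "gca"),
    synthetic = list(
      n_sets = 20L, embedding_dim = 16L, probe_rank = 8L,
      embedding_noise_sd = 0.05,
      mesh_vertices = 50L, n_participants = 12L,
      sampling_rate = 200, epoch_ms = 600,
      effect_size = 2, effect_window = c(150, 300), effect_vertices = 5L,
      noise_sd = 1, length_scale = 15),
    probe = list(n_restarts = 3L, max_iter = 500L, lr = 1e-3),
    searchlight = list(spatial_radius = 10, temporal_radius = 30,
                       temporal_stride = 10L),
    stats = list(n_perm = 500L, vertex_p = 0.01, cluster_p = 0.05,
                 n_spearman_perm = 1000L, fdr_alpha = 0.05),
    gca = list(k_min = 2L, k_max = 4L, n_restarts = 5L,
               n_surrogates = 200L, max_order = 3L)
  )
}

#' Validate a pipeline configuration
#'
#' Checks the configuration (a list or a YAML file path) for violations —
#' invalid radii, impossible permutation counts, effect windows outside the
#' epoch — without running anything.
#'
#' @param config list or path to a YAML file.
#' @return character vector of violations; empty when valid.
#' @export
validateConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(is.numeric(config$seed) && length(config$seed) == 1,
      "seed must be a single integer (no wall-clock seeding)")
  known <- c("generate", "probe", "measures", "geometry", "rsa",
             "cluster", "gca")
  chk(all(config$stages %in% known),
      paste("unknown stage:",
            paste(setdiff(config$stages, known), collapse = ", ")))
  sl <- config$searchlight
  chk(sl$spatial_radius > 0, "searchlight spatial_radius must be positive")
  chk(sl$temporal_radius > 0, "searchlight temporal_radius must be positive")
  chk(sl$temporal_stride >= 1, "temporal_stride must be >= 1")
  st <- config$stats
  chk(st$n_perm >= 1, "n_perm must be >= 1")
  chk(st$vertex_p > 0 && st$vertex_p < 1, "vertex_p must be in (0, 1)")
  chk(st$cluster_p > 0 && st$cluster_p < 1, "cluster_p must be in (0, 1)")
  sy <- config$synthetic
  chk(sy$n_sets >= 1, "n_sets must be >= 1")
  chk(sy$effect_vertices <= sy$mesh_vertices,
      "effect vertex set larger than the mesh")
  chk(all(sy$effect_window >= 0) && all(sy$effect_window <= sy$epoch_ms),
      "effect window outside the epoch")
  chk(sy$effect_size > 0, "effect size must be positive")
  chk(sy$probe_rank <= sy$embedding_dim,
      "probe rank exceeds embedding dimension")
  v
}

configHash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

stageFresh <- function(dir, stage, hash) {
  f <- file.path(dir, stage, ".hash")
  file.exists(f) && identical(readLines(f, warn = FALSE)[1], hash)
}

stageDone <- function(dir, stage, hash) {
  writeLines(hash, file.path(dir, stage, ".hash"))
}

#' Run the end-to-end pipeline
#'
#' Orchestrates generate -> probe -> measures -> geometry -> searchlight
#' RSA -> cluster inference -> NMF/Granger causality from one declarative
#' config. Every stage writes its outputs (delimited tables, CoNLL-U trees,
#' array containers, JSON reports, figures) under its own subdirectory of
#' `out_dir`; a manifest JSON records the config, seed, per-stage output
#' checksums and package version. Stages whose stored config hash matches
#' are skipped on reruns; the run is deterministic given the seed.
#'
#' @param config list (see [defaultConfig()]) or path to a YAML file.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config = defaultConfig()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  viol <- validateConfig(config)
  if (length(viol))
    stop("invalid config:\n  ", paste(viol, collapse = "\n  "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- configHash(config)
  seed <- as.integer(config$seed)
  log <- function(stage, ...) message(sprintf("[%s] %s", stage,
                                              sprintf(...)))
  state <- new.env(parent = emptyenv())
  outputs <- list()

  runStage <- function(stage, fn) {
    sdir <- file.path(config$out_dir, stage)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    t0 <- Sys.time()
    res <- tryCatch(fn(sdir), error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
    log(stage, "done in %.1fs", as.numeric(Sys.time() - t0, units = "secs"))
    files <- list.files(sdir, full.names = TRUE)
    files <- files[!grepl("\\.pdf$", files)]  # figures embed timestamps
    outputs[[stage]] <<- as.list(tools::md5sum(files))
    stageDone(config$out_dir, stage, hash)
    res
  }

  ## ---- generate ----
  sy <- config$synthetic
  state$stimuli <- generateStimuli(sy$n_sets, seed = seed)
  state$ids <- targetIds(state$stimuli)
  state$mesh <- generateMesh(sy$mesh_vertices, seed = seed + 1L)
  if ("generate" %in% config$stages) {
    runStage("generate", function(sdir) {
      allTrees <- unlist(lapply(state$stimuli$trees, function(x)
        if (is(x, "DependencyTree")) list(x) else x), use.names = FALSE)
      writeConllu(allTrees, file.path(sdir, "trees.conllu"))
      utils::write.table(state$stimuli$sentences,
                         file.path(sdir, "sentences.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      state$counts <- generateCorpusCounts(state$stimuli, seed = seed + 2L)
      utils::write.table(state$counts, file.path(sdir, "corpus_counts.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      state$contin <- generateContinuations(state$stimuli, seed = seed + 2L)
      utils::write.table(state$contin, file.path(sdir, "continuations.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(state$mesh, file.path(sdir, "mesh.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      gen <- generateEmbeddings(state$stimuli, d = sy$embedding_dim,
                                k = sy$probe_rank,
                                noiseSd = sy$embedding_noise_sd,
                                seed = seed + 3L)
      state$emb <- gen
      writeArray(gen$B0, file.path(sdir, "planted_probe.rds"),
                 meta = list(kind = "planted probe matrix"))
      # plant the incremental-depth cosine RDM (pre-resolution prefix, where
      # the interpretation preference varies across sentences)
      mvDepths <- t(vapply(state$ids, function(id) {
        L <- state$stimuli$sentences$pp3_pos[
          state$stimuli$sentences$sentence_id == id]
        gen$gold[[embKey(id, L)]][1:3]
      }, numeric(3)))
      state$plantRdm <- modelRdm(mvDepths, "cosine_distance",
                                 label = "parse_depth_vector",
                                 conditions = state$ids)
      center <- which.min(rowSums(as.matrix(dist(
        as.matrix(state$mesh[, c("x", "y", "z")])))))
      nb <- order(as.matrix(dist(
        as.matrix(state$mesh[, c("x", "y", "z")])))[center, ])
      state$effectVertices <- sort(nb[seq_len(sy$effect_vertices)])
      state$epochs <- generateEpochs(
        state$ids, state$mesh, nParticipants = sy$n_participants,
        samplingRate = sy$sampling_rate, epochMs = sy$epoch_ms,
        epochLabel = "MV",
        effects = list(list(vertices = state$effectVertices,
                            window = sy$effect_window,
                            rdm = state$plantRdm, size = sy$effect_size)),
        noiseSd = sy$noise_sd, lengthScale = sy$length_scale,
        seed = seed + 4L)
      writeArray(state$epochs@data, file.path(sdir, "epochs.rds"),
                 dimLabels = c("participant", "sentence", "vertex", "time"),
                 meta = list(sampling_rate = sy$sampling_rate,
                             epoch = "MV",
                             effect_vertices = state$effectVertices,
                             effect_window = sy$effect_window))
      writeRdm(state$plantRdm, file.path(sdir, "planted_model_rdm.tsv"))
      invisible(NULL)
    })
  }

  ## ---- probe ----
  if ("probe" %in% config$stages) {
    runStage("probe", function(sdir) {
      full <- lapply(state$ids, function(id) {
        n <- state$stimuli$sentences$n_tokens[
          state$stimuli$sentences$sentence_id == id]
        embKey(id, n)
      })
      keys <- unlist(full)
      pr <- config$probe
      probe <- trainProbe(state$emb$embeddings, state$emb$gold[keys],
                          k = sy$probe_rank, nRestarts = pr$n_restarts,
                          seed = seed + 5L, maxIter = pr$max_iter,
                          lr = pr$lr)
      state$probe <- probe
      writeProbe(probe, file.path(sdir, "probe.tsv"))
      mv <- setNames(
        state$stimuli$sentences$mv_pos[state$stimuli$sentences$is_target],
        state$ids)
      acc <- rootAccuracy(probe, state$emb$embeddings, mv)
      # averaged incremental depths per sentence at the main-verb prefix
      depthRows <- lapply(state$ids, function(id) {
        L <- state$stimuli$sentences$mv_pos[
          state$stimuli$sentences$sentence_id == id]
        d <- predictDepthsAveraged(
          probe, embeddingEntry(state$emb$embeddings, id, L), id)@depths
        data.frame(sentence_id = id, position = seq_along(d), depth = d)
      })
      state$probeDepths <- do.call(rbind, depthRows)
      utils::write.table(state$probeDepths,
                         file.path(sdir, "probe_depths.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      jsonlite::write_json(list(root_accuracy = acc,
                                restart_losses = probe@meta$restart_losses),
                           file.path(sdir, "probe_report.json"),
                           auto_unbox = TRUE, digits = NA)
      invisible(NULL)
    })
  }

  ## ---- measures ----
  if ("measures" %in% config$stages) {
    runStage("measures", function(sdir) {
      tab <- interpretationIndices(ratioMeasures(state$counts))
      cp <- continuationProbabilities(state$contin)
      tab <- merge(tab, cp, by = "sentence_id", sort = FALSE)
      state$constraints <- tab
      utils::write.table(tab, file.path(sdir, "constraints.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      st <- config$stats
      vars <- c("transitivity", "passive_index", "active_index",
                "nondirectional_index", "agenthood")
      rep <- do.call(rbind, lapply(seq_along(vars), function(i) {
        ps <- permutationSpearman(tab[[vars[i]]], tab$MV_prob,
                                  nPerm = st$n_spearman_perm,
                                  seed = seed + 10L + i)
        data.frame(variable = vars[i], rho = ps$rho, p = ps$p)
      }))
      fdr <- fdrCorrect(rep$p, st$fdr_alpha)
      rep$p_fdr <- fdr$p_adjusted
      rep$significant <- fdr$significant
      utils::write.table(rep, file.path(sdir, "correlations.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      invisible(NULL)
    })
  }

  ## ---- geometry ----
  if ("geometry" %in% config$stages) {
    runStage("geometry", function(sdir) {
      sen <- state$stimuli$sentences
      geo <- do.call(rbind, lapply(state$ids, function(id) {
        row <- sen[sen$sentence_id == id, ]
        tr <- state$stimuli$trees[[id]]
        lmP <- landmarkVector(tr$passive, 3L)
        lmA <- landmarkVector(tr$active, 3L)
        steps <- row$v1_pos:row$mv_pos
        v3 <- t(vapply(steps, function(L)
          predictDepthsAveraged(state$probe,
            embeddingEntry(state$emb$embeddings, id, L), id)@depths[1:3],
          numeric(3)))
        traj <- landmarkTrajectory(v3, lmP, lmA, sentenceId = id)
        atV1 <- v3[1, 3]
        atMV <- v3[nrow(v3), 3]
        mm <- interpretativeMismatch(v3[nrow(v3), ], depths(lmP))
        cbind(traj, v1_depth_change = v1DepthChange(atMV, atV1),
              mismatch_passive = mm)
      }))
      utils::write.table(geo, file.path(sdir, "trajectories.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      # model RDMs over the canonical order
      v1depth <- vapply(state$ids, function(id) {
        row <- sen[sen$sentence_id == id, ]
        state$probeDepths$depth[state$probeDepths$sentence_id == id &
                                  state$probeDepths$position == row$v1_pos]
      }, numeric(1))
      rdmV1 <- modelRdm(v1depth, "absolute_difference", "v1_parse_depth",
                        conditions = state$ids)
      rdmPass <- modelRdm(state$constraints$passive_index,
                          "absolute_difference", "passive_index",
                          conditions = state$ids)
      state$rdmPass <- rdmPass
      writeRdm(rdmV1, file.path(sdir, "rdm_v1_depth.tsv"))
      writeRdm(rdmPass, file.path(sdir, "rdm_passive_index.tsv"))
      depthsMat <- matrix(state$probeDepths$depth[
        state$probeDepths$position <= 3], ncol = 3, byrow = TRUE)
      pc <- pcaScores(depthsMat)
      utils::write.table(
        data.frame(sentence_id = state$ids, pc$scores),
        file.path(sdir, "pca_scores.tsv"),
        sep = "\t", row.names = FALSE, quote = FALSE)
      grDevices::pdf(file.path(sdir, "trajectories.pdf"), 6, 4)
      graphics::plot(NA, xlim = range(geo$step),
                     ylim = range(c(geo$distance_to_passive,
                                    geo$distance_to_active)),
                     xlab = "prefix position",
                     ylab = "distance to landmark",
                     main = "Landmark distances")
      for (id in head(state$ids, 10)) {
        g <- geo[geo$sentence_id == id, ]
        graphics::lines(g$step, g$distance_to_passive, col = "orange")
        graphics::lines(g$step, g$distance_to_active, col = "purple")
      }
      grDevices::dev.off()
      invisible(NULL)
    })
  }

  ## ---- rsa ----
  spec <- new("SearchlightSpec",
              spatialRadius = config$searchlight$spatial_radius,
              temporalRadius = config$searchlight$temporal_radius,
              temporalStride = as.integer(config$searchlight$temporal_stride))
  if ("rsa" %in% config$stages) {
    runStage("rsa", function(sdir) {
      fp <- file.path(sdir, "fit_planted.rds")
      fs <- file.path(sdir, "fit_passive.rds")
      if (stageFresh(config$out_dir, "rsa", hash) &&
          file.exists(fp) && file.exists(fs)) {
        a <- readArray(fp); b <- readArray(fs)
        state$fitPlanted <- new("FitMap", rho = a$data, model = a$meta$model,
                                centers = as.numeric(a$meta$centers))
        state$fitPassive <- new("FitMap", rho = b$data, model = b$meta$model,
                                centers = as.numeric(b$meta$centers))
        log("rsa", "reusing cached fit maps")
        return(invisible(NULL))
      }
      state$fitPlanted <- runSsrsa(state$epochs, state$plantRdm,
                                   state$mesh, spec)
      state$fitPassive <- runSsrsa(state$epochs, state$rdmPass,
                                   state$mesh, spec)
      writeArray(state$fitPlanted@rho, file.path(sdir, "fit_planted.rds"),
                 dimLabels = c("participant", "vertex", "window"),
                 meta = list(model = state$fitPlanted@model,
                             centers = state$fitPlanted@centers))
      writeArray(state$fitPassive@rho, file.path(sdir, "fit_passive.rds"),
                 dimLabels = c("participant", "vertex", "window"),
                 meta = list(model = state$fitPassive@model,
                             centers = state$fitPassive@centers))
      invisible(NULL)
    })
  }

  ## ---- cluster ----
  if ("cluster" %in% config$stages) {
    runStage("cluster", function(sdir) {
      st <- config$stats
      adj <- searchlightIndex(state$mesh, state$epochs@times, spec)$neighbors
      cl <- groupClusterTest(state$fitPlanted, adj, nPerm = st$n_perm,
                             vertexP = st$vertex_p, clusterP = st$cluster_p,
                             seed = seed + 20L)
      state$cluster <- cl
      sm <- summaryMaps(cl, regions = state$mesh$region)
      jsonlite::write_json(
        list(threshold = cl@threshold,
             clusters = lapply(cl@clusters, function(x)
               list(mass = x$mass, p = x$p, n_cells = nrow(x$cells),
                    vertices = unique(x$cells[, 1]),
                    windows = unique(x$cells[, 2]))),
             vertex_tmass = sm$vertex_tmass),
        file.path(sdir, "clusters.json"), auto_unbox = TRUE, digits = NA)
      writeArray(cl@mask * 1, file.path(sdir, "significant_mask.rds"),
                 dimLabels = c("vertex", "window"))
      grDevices::pdf(file.path(sdir, "tmap.pdf"), 6, 4)
      graphics::image(t(cl@tmap), xlab = "window", ylab = "vertex",
                      main = sprintf("t map (threshold %.2f)", cl@threshold))
      grDevices::dev.off()
      invisible(NULL)
    })
  }

  ## ---- gca ----
  if ("gca" %in% config$stages) {
    runStage("gca", function(sdir) {
      g <- config$gca
      fA <- nmfDecompose(state$fitPassive, kRange = g$k_min:g$k_max,
                         nRestarts = g$n_restarts, seed = seed + 30L)
      fB <- nmfDecompose(state$fitPlanted, kRange = g$k_min:g$k_max,
                         nRestarts = g$n_restarts, seed = seed + 31L)
      gc <- gcPairwise(fA, fB, maxOrder = g$max_order)
      gc <- gcSignificance(fA, fB, gc, nSurrogates = g$n_surrogates,
                           seed = seed + 32L)
      utils::write.table(gc, file.path(sdir, "gc_connections.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      writeArray(fA@H, file.path(sdir, "factors_passive.rds"),
                 dimLabels = c("factor", "window", "participant"),
                 meta = list(k = fA@k, rms = as.list(fA@rms)))
      writeArray(fB@H, file.path(sdir, "factors_planted.rds"),
                 dimLabels = c("factor", "window", "participant"),
                 meta = list(k = fB@k, rms = as.list(fB@rms)))
      invisible(NULL)
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("incstruct")),
    r_version = R.version.string,
    config = config, config_hash = hash, seed = seed,
    stages = outputs, finished = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
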