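# Config-driven end-to-end runner: read/simulate -> preprocess -> segment
# -> co-register -> stats -> annotate -> enrich -> cross-validate, with a
# machine-readable manifest. Identical config + inputs give byte-identical
# tabular outputs (every stochastic step takes its seed from the config;
# no timestamps enter any artifact).

pipelineDefaults <- function() {
  list(
    preprocess = list(baseline_window = 51, snr_min = 3, align_tol_ppm = 10,
                      min_pixel_fraction = 0.3, normalize = TRUE,
                      median_kernel = 3),
    segmentation = list(k = 4, seed = 42, denoise = TRUE, merges = NULL),
    stats = list(p_max = 0.05, auc_min = 0.7, group_a_labels = 1,
                 icc_targets = 50, icc_seed = 11,
                 vip_min = 1.0, loading_min = 0.05),
    annotation = list(tol_ppm = 10, adducts = NULL, db = NULL),
    enrichment = list(sets = NULL, n_perm = 499, seed = 5),
    lcms = list(path = NULL, n_per_group = 6, seed = 9, sdlog = 0.3)
  )
}

mergeConfig <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(defaults[[nm]]))
      defaults[[nm]] <- mergeConfig(defaults[[nm]], user[[nm]])
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Read and validate a pipeline configuration
#'
#' Loads a YAML pipeline configuration (or takes a list), merges it over
#' the package defaults and validates every threshold and referenced path
#' before any computation starts.
#'
#' @param config path to a YAML file, or a named list.
#' @return The validated, default-completed config list.
#' @export
readPipelineConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- mergeConfig(pipelineDefaults(), config)
  if (is.null(cfg$output_dir)) stop("config needs an output_dir")
  if (is.null(cfg$simulate) && is.null(cfg$input))
    stop("config needs either a 'simulate' or an 'input' section")
  if (!is.null(cfg$input) && !file.exists(cfg$input$imzml))
    stop("input imzML not found: ", cfg$input$imzml)
  with(cfg$segmentation, {
    if (k < 2) stop("segmentation k must be >= 2")
  })
  with(cfg$preprocess, {
    if (align_tol_ppm <= 0 || snr_min <= 0 || baseline_window < 3 ||
        min_pixel_fraction < 0 || min_pixel_fraction > 1 ||
        median_kernel %% 2 != 1)
      stop("invalid preprocess thresholds")
  })
  with(cfg$stats, {
    if (p_max <= 0 || p_max > 1 || auc_min < 0.5 || auc_min > 1 ||
        vip_min < 0 || loading_min < 0)
      stop("invalid stats thresholds")
  })
  if (cfg$annotation$tol_ppm <= 0) stop("annotation tol_ppm must be > 0")
  if (cfg$enrichment$n_perm < 100) stop("enrichment n_perm must be >= 100")
  for (p in c(cfg$annotation$db, cfg$enrichment$sets, cfg$lcms$path))
    if (!is.null(p) && !file.exists(p)) stop("referenced path missing: ", p)
  cfg
}

## Per-feature ICC across replicate acquisitions: features of each
## replicate table are matched to the first by ppm, a fixed random subset
## of pixels acts as targets, replicates as raters, on log2 intensities.
#' ICC across replicate peak tables
#'
#' @param ptList list of [PeakTable-class] replicates on the same grid.
#' @param nTargets number of pixels sampled as ICC targets (default 50).
#' @param seed seed for the target draw.
#' @param tolPpm feature matching tolerance across replicates.
#' @return data.frame from [iccFeatures()] plus a `mz` column.
#' @export
replicateICC <- function(ptList, nTargets = 50, seed = 1, tolPpm = 10) {
  stopifnot(length(ptList) >= 2L)
  refMz <- featureMz(ptList[[1]])
  idx <- lapply(ptList, function(pt) {
    other <- featureMz(pt)
    vapply(refMz, function(m) {
      err <- abs(ppmDiff(m, other))
      j <- which.min(err)
      if (err[j] <= tolPpm) j else NA_integer_
    }, integer(1))
  })
  common <- which(Reduce(`&`, lapply(idx, function(i) !is.na(i))))
  if (!length(common)) stop("no features shared across replicates")
  npix <- ncol(intensityMatrix(ptList[[1]]))
  targets <- withSeed(seed, sample.int(npix, min(nTargets, npix)))
  mats <- lapply(common, function(f) {
    m <- vapply(seq_along(ptList), function(r)
      intensityMatrix(ptList[[r]])[idx[[r]][f], targets], numeric(length(targets)))
    m
  })
  ok <- vapply(mats, function(m) all(m > 0), logical(1))
  res <- iccFeatures(lapply(mats[ok], log2))
  res$mz <- refMz[common][ok]
  res$feature <- sprintf("mz_%.4f", res$mz)
  res
}

writeCsv <- function(df, dir, name) {
  utils::write.csv(df, file.path(dir, name), row.names = FALSE)
}

#' Run the full spatial-metabolomics pipeline
#'
#' Executes the analysis graph on a real (imzML) or simulated dataset:
#' preprocessing to a consensus peak table, K-means segmentation with
#' optional operator merges, fiber-type composition against the reference
#' label map, per-feature discrimination (t, AUC) and -- given replicate
#' acquisitions -- ICC reproducibility, ppm annotation, quantitative set
#' enrichment, PLS-DA biomarker selection on the LC-MS arm and the
#' identity-level Venn overlap between platforms. Every stage writes its
#' CSV/JSON artifact into `output_dir` and the manifest records every
#' seed and threshold used. A stage failure aborts with the stage name
#' and leaves a `FAILED_<stage>` marker.
#'
#' @param config YAML path or config list (see [readPipelineConfig()]).
#' @return Invisibly, a report list with the stage results.
#' @export
runPipeline <- function(config) {
  cfg <- readPipelineConfig(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(config = cfg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      file.create(file.path(cfg$output_dir, paste0("FAILED_", name)))
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## --- acquire ---------------------------------------------------------
  truth <- NULL
  datasets <- stage("input", {
    if (!is.null(cfg$simulate)) {
      sc <- cfg$simulate
      phantom <- makePhantom(sc$width %||% 40, sc$height %||% 28,
                             layout = sc$preset %||% "muscle",
                             seed = sc$seed %||% 7,
                             rareFrac = sc$rare_frac %||% 0.05)
      sim <- simulateMSI(phantom,
                         nFeatures = sc$n_features %||% 60,
                         nMarkersPerClass = sc$n_markers_per_class %||% 5,
                         snr = sc$snr %||% 4,
                         replicates = sc$replicates %||% 1,
                         seed = sc$seed %||% 7,
                         mode = sc$mode %||% "centroid",
                         effectLog2 = sc$effect_log2 %||% 2)
      truth <- sim$truth
      sim$datasets
    } else {
      list(readImzML(cfg$input$imzml))
    }
  })

  ## --- preprocess ------------------------------------------------------
  pp <- cfg$preprocess
  ptList <- stage("preprocess", lapply(datasets, function(ds)
    processDataset(ds, baselineWindow = pp$baseline_window,
                   snrMin = pp$snr_min, tolPpm = pp$align_tol_ppm,
                   minPixelFraction = pp$min_pixel_fraction,
                   normalize = pp$normalize)))
  pt <- ptList[[1]]
  M <- intensityMatrix(pt)
  writeCsv(data.frame(feature = rownames(M), mz = featureMz(pt),
                      mean_intensity = rowMeans(M),
                      pixel_fraction = rowMeans(M > 0)),
           cfg$output_dir, "peak_table.csv")
  report$n_features <- nrow(M)

  ## --- segment ---------------------------------------------------------
  sg <- cfg$segmentation
  seg <- stage("segment", {
    s <- segment(pt, k = sg$k, seed = sg$seed, denoise = isTRUE(sg$denoise),
                 kernel = pp$median_kernel)
    if (!is.null(sg$merges))
      s <- mergeClasses(s, unlist(sg$merges))
    s
  })
  utils::write.table(labelMatrix(seg),
                     file.path(cfg$output_dir, "segmentation_labels.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  writeCsv(as.data.frame(seg@centroids), cfg$output_dir, "centroids.csv")
  if (!is.null(seg@dendrogram))
    jsonlite::write_json(
      list(merge = seg@dendrogram$merge, height = seg@dendrogram$height),
      file.path(cfg$output_dir, "dendrogram.json"), digits = NA)
  report$segmentation <- seg

  ## --- reference labels / composition ---------------------------------
  fiber <- stage("register", {
    if (!is.null(cfg$registration)) {
      lm <- utils::read.csv(cfg$registration$landmarks)
      tr <- fitLandmarks(lm[, c("src_x", "src_y")], lm[, c("dst_x", "dst_y")])
      mask <- readLabelMap(cfg$registration$mask)
      d <- dim(labelMatrix(seg))
      resampleMask(mask, tr, d[1], d[2])
    } else if (!is.null(truth)) {
      truth@classMap
    } else NULL
  })
  if (!is.null(fiber)) {
    comp <- stage("composition", composition(seg@labels, fiber))
    writeCsv(as.data.frame(comp$scores), cfg$output_dir, "composition_scores.csv")
    report$composition <- comp
    if (!is.null(truth) && requireNamespace("mclust", quietly = TRUE)) {
      coords <- pixelCoords(pt)
      report$ari <- mclust::adjustedRandIndex(
        gridToValues(labelMatrix(seg), coords),
        gridToValues(labelMatrix(truth@classMap), coords))
    }
  }

  ## --- per-feature stats -----------------------------------------------
  st <- cfg$stats
  statsTab <- stage("stats", {
    coords <- pixelCoords(pt)
    lab <- gridToValues(labelMatrix(fiber %||% seg@labels), coords)
    grp <- factor(ifelse(lab %in% st$group_a_labels, "A", "B"))
    X <- t(M)
    tt <- ttestFeatures(X, grp)
    au <- aucFeatures(X, grp, aucMin = st$auc_min)
    tab <- cbind(tt, auc = au$auc, discriminative = au$discriminative,
                 mz = featureMz(pt))
    ## any-class discrimination: one-vs-rest per reference class
    for (cl in sort(unique(lab[lab > 0]))) {
      g <- factor(ifelse(lab == cl, "in", "out"))
      a <- aucFeatures(X, g, aucMin = st$auc_min)
      tab$discriminative <- tab$discriminative | a$discriminative
    }
    if (length(ptList) >= 2L) {
      icc <- replicateICC(ptList, nTargets = st$icc_targets,
                          seed = st$icc_seed,
                          tolPpm = pp$align_tol_ppm)
      tab <- merge(tab, icc[, c("feature", "icc", "icc_band")],
                   by = "feature", all.x = TRUE, sort = FALSE)
    }
    tab[order(tab$mz), ]
  })
  writeCsv(statsTab, cfg$output_dir, "feature_stats.csv")
  report$feature_stats <- statsTab

  ## --- annotation ------------------------------------------------------
  db <- stage("annotate_db", {
    if (!is.null(cfg$annotation$db)) readMetaboliteDB(cfg$annotation$db)
    else if (!is.null(truth)) {
      ## synthetic reference DB spanning every simulated feature
      et <- truth@effectTable
      mzTrue <- sort(unique(c(et$mz,
        if (nrow(et)) numeric() else numeric())))
      allMz <- featureMz(pt)
      nm <- vapply(allMz, function(m) {
        j <- which(abs(ppmDiff(m, et$mz)) <= cfg$annotation$tol_ppm)
        if (length(j)) et$name[j[1]] else sprintf("unknown_%.4f", m)
      }, character(1))
      data.frame(id = sprintf("F%04d", seq_along(allMz)), name = nm,
                 neutral_mass = allMz - 1.00727646,
                 class = ifelse(grepl("^acylcarnitine", nm),
                                "acyl carnitine", "other"),
                 stringsAsFactors = FALSE)
    } else NULL
  })
  ann <- NULL
  if (!is.null(db)) {
    ann <- stage("annotate", annotateFeatures(
      featureMz(pt), db, polarity = "positive",
      adducts = cfg$annotation$adducts, tolPpm = cfg$annotation$tol_ppm))
    writeCsv(ann, cfg$output_dir, "annotations.csv")
    report$annotations <- ann
  }

  ## --- enrichment ------------------------------------------------------
  if (!is.null(ann)) {
    enr <- stage("enrich", {
      sets <- if (!is.null(cfg$enrichment$sets)) readGMT(cfg$enrichment$sets)
        else if (!is.null(truth) && nrow(truth@effectTable)) {
          et <- truth@effectTable
          byClass <- split(et, et$class)
          s <- lapply(byClass, function(d) {
            ids <- vapply(d$mz, function(m) {
              j <- which.min(abs(ppmDiff(m, featureMz(pt))))
              db$id[j]
            }, character(1))
            unique(ids)
          })
          nms <- vapply(byClass, function(d) {
            cn <- truth@classMap@labelNames[as.character(d$class[1])]
            if (cn == "fast_2b_oxidative") "acyl carnitines"
            else paste(cn, "markers")
          }, character(1))
          stats::setNames(s, nms)
        } else NULL
      if (is.null(sets)) return(NULL)
      ## metabolite matrix: best-candidate id per feature, pixels as samples
      best <- ann[!duplicated(ann$feature_mz), ]
      fidx <- match(best$feature_mz, featureMz(pt))
      metM <- t(M[fidx, , drop = FALSE])
      colnames(metM) <- best$metabolite_id
      coords <- pixelCoords(pt)
      lab <- gridToValues(labelMatrix(fiber %||% seg@labels), coords)
      out <- lapply(names(sets), function(nm) {
        present <- intersect(sets[[nm]], colnames(metM))
        if (!length(present)) return(NULL)
        ## class the set belongs to (vs rest), slow-vs-rest for externals
        cls <- if (!is.null(truth) && nrow(truth@effectTable)) {
          ids2mz <- best$feature_mz[match(present, best$metabolite_id)]
          et <- truth@effectTable
          j <- which.min(abs(ppmDiff(ids2mz[1], et$mz)))
          et$class[j]
        } else st$group_a_labels[1]
        y <- factor(ifelse(lab == cls, "in", "out"))
        if (nlevels(y) != 2L) return(NULL)
        qea(metM, y, sets[nm], nPerm = cfg$enrichment$n_perm,
            seed = cfg$enrichment$seed)
      })
      res <- do.call(rbind, out)
      if (!is.null(res)) res$p_bonf <- pmin(1, res$p_perm * nrow(res))
      res
    })
    if (!is.null(enr)) {
      writeCsv(enr, cfg$output_dir, "enrichment.csv")
      report$enrichment <- enr
    }
  }

  ## --- LC-MS arm + cross-validation ------------------------------------
  lc <- cfg$lcms
  lcms <- stage("lcms", {
    if (!is.null(lc$path)) {
      loadLCMS(lc$path, unlist(lc$groups))
    } else if (!is.null(truth) && nrow(truth@effectTable) && !is.null(db)) {
      ## planted LC-MS arm sharing the MSI id namespace: markers of the
      ## oxidative/slow classes boosted in group B
      et <- truth@effectTable
      fidx <- vapply(et$mz, function(m)
        which.min(abs(ppmDiff(m, featureMz(pt)))), integer(1))
      simulateLCMS(nFeatures = nrow(db), nPerGroup = lc$n_per_group,
                   planted = data.frame(feature = fidx,
                                        log2fc = et$log2_effect),
                   seed = lc$seed, sdlog = lc$sdlog,
                   ids = db$id,
                   mzValues = db$neutral_mass + 1.00727646)$table
    } else NULL
  })
  if (!is.null(lcms)) {
    lcRes <- stage("crossval", {
      diffRes <- differentialLCMS(lcms, pMax = st$p_max)
      mdl <- plsda(log2(t(intensityMatrix(lcms)) + 1),
                   factor(lcms@groups[colnames(intensityMatrix(lcms))]),
                   nComponents = 2)
      bio <- selectBiomarkers(mdl, vipMin = st$vip_min,
                              loadingMin = st$loading_min)
      msiIds <- if (!is.null(ann)) {
        best <- ann[!duplicated(ann$feature_mz), ]
        disc <- statsTab$mz[statsTab$discriminative]
        best$metabolite_id[best$feature_mz %in% disc]
      } else character()
      vn <- vennOverlap(msiIds, diffRes$ids)
      list(differential = diffRes, plsda = mdl, biomarkers = bio,
           venn = vn)
    })
    writeCsv(lcRes$differential$stats, cfg$output_dir, "lcms_stats.csv")
    writeCsv(data.frame(biomarker = lcRes$biomarkers),
             cfg$output_dir, "plsda_biomarkers.csv")
    jsonlite::write_json(lcRes$venn[c("counts")],
                         file.path(cfg$output_dir, "venn.json"), digits = NA)
    report$lcms <- lcRes
  }

  ## --- manifest ---------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("fiberMSI")),
    thresholds = cfg[c("preprocess", "segmentation", "stats",
                       "annotation", "enrichment")],
    seeds = list(simulate = cfg$simulate$seed,
                 segmentation = cfg$segmentation$seed,
                 enrichment = cfg$enrichment$seed,
                 lcms = cfg$lcms$seed))
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
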