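#' Default pipeline configuration
#'
#' Parameters for an end-to-end run on a generated cohort: QC
#' thresholds, probe filters, landscape settings, DMP thresholds, bin
#' scheme, contrast orientation for pathway direction calls, and seeds.
#' Values can be overridden by a YAML file
#' (\code{\link{readPipelineConfig}}) or by named arguments.
#'
#' @param ... named overrides of the defaults
#' @return list of class \code{"PipelineConfig"}
#' @export
pipelineConfig <- function(...) {
    cfg <- list(
        detpThreshold = 0.01, maxFailFraction = 0.10,
        probeFilters = "sex",
        topK = 10000,
        perplexity = 30, tsneIter = 1000,
        consensusB = 500, consensusSubsample = 0.8, k = NULL,
        pAdjMax = 0.01, absLfcMin = 0.3, scale = "beta",
        referenceGroups = NULL,       # consensus-degree reference
        lesionGroup = NULL, normalGroup = NULL,  # pathway contrast
        seed = 1)
    over <- list(...)
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
        stop("unknown config fields: ", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
    stopifnot(cfg$detpThreshold > 0, cfg$detpThreshold < 1,
              cfg$maxFailFraction > 0, cfg$maxFailFraction < 1,
              cfg$topK >= 1, cfg$pAdjMax > 0, cfg$absLfcMin >= 0)
    structure(cfg, class = "PipelineConfig")
}

#' @rdname pipelineConfig
#' @param path YAML file with config fields
#' @export
readPipelineConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    do.call(pipelineConfig, vals)
}

#' Run the full methylation landscape pipeline
#'
#' Orchestrates QC, probe filtering, top-variance selection, t-SNE,
#' hierarchical and consensus clustering with the consensus-degree test,
#' all-pairs DMP counting, the relatedness network, TSS pathway
#' direction calls (when a lesion/normal contrast is configured) and,
#' when a signature is supplied, cell-type fraction estimation. Stage
#' outputs land in \code{outDir} together with a machine-readable
#' manifest (parameters, seed, package version, per-stage status).
#'
#' Stages are resumable: with \code{resume = TRUE} a stage whose output
#' files already exist is skipped, provided no upstream stage was rerun
#' in this invocation; once a stage reruns, everything downstream reruns
#' too. Identical config and seed give identical outputs.
#'
#' @param me a \linkS4class{MethylExperiment} (e.g. from
#'   \code{\link{generateCohort}} or \code{\link{readCohort}})
#' @param outDir output directory
#' @param config a \code{"PipelineConfig"}
#' @param signature optional features x cell types matrix for the
#'   deconvolution stage
#' @param geneSets optional gene-set collection (\code{\link{readGMT}})
#'   for the enrichment stage
#' @param resume skip stages whose outputs already exist
#' @return (invisibly) a list of in-memory stage results
#' @export
runPipeline <- function(me, outDir, config = pipelineConfig(),
                        signature = NULL, geneSets = NULL,
                        resume = FALSE) {
    stopifnot(is(me, "MethylExperiment"),
              inherits(config, "PipelineConfig"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(package = "MethylScape",
                     version = as.character(utils::packageVersion("MethylScape")),
                     config = unclass(config), stages = list())
    results <- list()
    dirty <- FALSE        # once a stage reruns, downstream must too
    stage <- function(name, outputs, fun) {
        paths <- file.path(outDir, outputs)
        if (resume && !dirty && all(file.exists(paths))) {
            manifest$stages[[name]] <<- "skipped (outputs present)"
            message("[", name, "] skipped, outputs present")
            return(invisible(NULL))
        }
        dirty <<- TRUE
        message("[", name, "] running")
        res <- fun(paths)
        manifest$stages[[name]] <<- "run"
        results[[name]] <<- res
        res
    }

    # --- QC ---------------------------------------------------------
    stage("qc", "qc_report.json", function(paths) {
        qc <- sampleQC(me, config$detpThreshold, config$maxFailFraction)
        jsonlite::write_json(
            list(failFraction = as.list(qc$failFraction),
                 excluded = qc$excluded,
                 pThreshold = qc$pThreshold,
                 maxFailFraction = qc$maxFailFraction),
            paths[1], auto_unbox = TRUE, digits = NA)
        qc
    })
    qc <- results$qc
    if (is.null(qc))
        qc <- sampleQC(me, config$detpThreshold, config$maxFailFraction)
    keep <- setdiff(colnames(me), qc$excluded)
    message(length(qc$excluded), " samples excluded by QC, ",
            length(keep), " kept")
    me <- me[, keep]

    # --- probe filtering + feature selection ------------------------
    me <- filterProbes(me, config$probeFilters)
    sel <- stage("select", "top_sd_probes.csv", function(paths) {
        sel <- selectTopSD(me, config$topK)
        utils::write.csv(sel, paths[1], row.names = FALSE)
        sel
    })
    if (is.null(sel)) sel <- selectTopSD(me, config$topK)
    top <- getBeta(me)[sel$probe_id, , drop = FALSE]
    sheet <- sampleSheet(me)
    k <- if (is.null(config$k)) length(unique(sheet$group_label)) else
        config$k

    # --- landscape --------------------------------------------------
    stage("tsne", "embedding.csv", function(paths) {
        emb <- tsneEmbed(top, perplexity = min(config$perplexity,
                                 floor((ncol(top) - 1) / 3)),
                         seed = config$seed, maxIter = config$tsneIter)
        emb$group <- sheet$group_label[match(emb$sample_id,
                                             sheet$sample_id)]
        utils::write.csv(emb, paths[1], row.names = FALSE)
        emb
    })
    stage("hclust", "dendrogram.nwk", function(paths) {
        hc <- hierarchicalCluster(top)
        writeNewick(hc, paths[1])
        hc
    })
    consensus <- stage("consensus",
                       c("consensus_matrix.tsv",
                         "consensus_degree_test.csv"), function(paths) {
        cons <- consensusCluster(top, k = k, B = config$consensusB,
                                 subsampleFraction = config$consensusSubsample,
                                 seed = config$seed)
        writeBetaMatrix(consensusMatrix(cons), paths[1])
        tab <- NULL
        if (!is.null(config$referenceGroups)) {
            tab <- consensusDegreeTest(cons, sheet,
                                       config$referenceGroups)
            utils::write.csv(tab, paths[2], row.names = FALSE)
        } else {
            utils::write.csv(data.frame(), paths[2], row.names = FALSE)
        }
        list(consensus = cons, degreeTest = tab)
    })

    # --- differential methylation + network -------------------------
    pd <- stage("dmp", c("dmp_counts.tsv"), function(paths) {
        pd <- pairwiseDMPCounts(getBeta(me), sheet,
                                pAdjMax = config$pAdjMax,
                                absLfcMin = config$absLfcMin,
                                scale = config$scale)
        writeBetaMatrix(dmpCounts(pd), paths[1])
        for (key in names(pd@sets)) {
            tab <- pd@sets[[key]]
            utils::write.table(
                tab[, c("probe_id", "delta", "t", "p", "padj")],
                file.path(outDir, paste0("dmp_",
                    gsub("[^A-Za-z0-9_]", "-", key), ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
        }
        pd
    })
    if (is.null(pd))
        pd <- pairwiseDMPCounts(getBeta(me), sheet,
                                pAdjMax = config$pAdjMax,
                                absLfcMin = config$absLfcMin,
                                scale = config$scale)
    stage("network", c("network_edges.tsv", "network.graphml"),
          function(paths) {
        ns <- table(sheet$group_label)
        g <- buildNetwork(pd, binScheme(),
                          nSamples = stats::setNames(as.integer(ns),
                                                     names(ns)))
        g <- annotateClosest(g, pd)
        writeEdgeList(g, paths[1])
        writeGraphML(g, paths[2])
        g
    })

    # --- TSS pathways (needs an explicit contrast) -------------------
    if (!is.null(config$lesionGroup) && !is.null(config$normalGroup)) {
        stage("pathways", c("gene_lists.csv", "enrichment.csv"),
              function(paths) {
            dmps <- dmpSet(pd, config$normalGroup, config$lesionGroup)
            # moderatedT delta is (second group - first group) in the
            # pair's sorted label order; flip so positive delta =
            # hypermethylated in the lesion
            sorted <- sort(c(config$normalGroup, config$lesionGroup))
            gl <- dmpsToGeneLists(dmps, probeAnnotation(me),
                                  flip = sorted[2] == config$normalGroup)
            utils::write.csv(
                data.frame(gene = c(gl$activated, gl$inhibited),
                           direction = rep(c("activated", "inhibited"),
                               c(length(gl$activated),
                                 length(gl$inhibited)))),
                paths[1], row.names = FALSE)
            enr <- NULL
            if (!is.null(geneSets)) {
                enr <- rbind(
                    hypergeometricEnrich(gl$activated, gl$universe,
                                         geneSets, "activated"),
                    hypergeometricEnrich(gl$inhibited, gl$universe,
                                         geneSets, "inhibited"))
                utils::write.csv(enr, paths[2], row.names = FALSE)
            } else utils::write.csv(data.frame(), paths[2],
                                    row.names = FALSE)
            list(geneLists = gl, enrichment = enr)
        })
    }

    # --- deconvolution ----------------------------------------------
    if (!is.null(signature)) {
        stage("deconv", "cell_fractions.csv", function(paths) {
            act <- geneActivityFromBeta(me)
            fe <- estimateFractions(act, signature)
            utils::write.csv(
                data.frame(sample_id = rownames(fe$fractions),
                           fe$fractions, residual = fe$residual,
                           check.names = FALSE),
                paths[1], row.names = FALSE)
            fe
        })
    }

    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(results)
}
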