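#' Configuration for the synthetic expression atlas generator
#'
#' Builds and validates the parameter set for [simulateAtlas()]. The defaults
#' describe a desk-scale multi-tissue developmental atlas: 6 tissues observed
#' over 7 ordered developmental stages with 5 replicates, 1000 genes, and
#' planted structure of three kinds — tissue-specific genes (upregulated by
#' \code{tissueEffectLog2} log2 units in one target tissue), stage-specific
#' genes (upregulated at one target stage in every tissue), and trajectory
#' genes following smooth archetype curves over stages.
#'
#' @param nTissues,nStages,nTimepointsPerStage,nReplicates design dimensions;
#'   samples are the full tissue x stage x timepoint x replicate crossing.
#' @param nGenes total genes simulated.
#' @param baselineLog2Mean,baselineLog2Sd mean and SD (log2-TPM units) of the
#'   per-gene baseline expression level.
#' @param nSpecificPerTissue,tissueEffectLog2 number of tissue-specific genes
#'   planted per tissue and their log2 effect in the target tissue.
#' @param nSpecificPerStage,stageEffectLog2 number of stage-specific genes
#'   planted per stage and their log2 effect at the target stage.
#' @param nTrajectoryGenes,nArchetypes trajectory genes cycled over the fixed
#'   archetype curves (monotone up, monotone down, single peak, single dip,
#'   then cosine shapes of increasing frequency), each scaled to unit
#'   amplitude on the log2 scale.
#' @param noiseSd Gaussian noise SD on the log2 scale.
#' @param seed RNG seed; identical seeds give bit-identical atlases.
#'
#' @return A validated list of class \code{"AtlasSimConfig"}.
#' @export
atlasSimConfig <- function(nTissues = 6, nStages = 7, nTimepointsPerStage = 1,
                           nReplicates = 5, nGenes = 1000,
                           baselineLog2Mean = 3, baselineLog2Sd = 2,
                           nSpecificPerTissue = 50, tissueEffectLog2 = 4,
                           nSpecificPerStage = 20, stageEffectLog2 = 4,
                           nTrajectoryGenes = 400, nArchetypes = 4,
                           noiseSd = 0.3, seed = 1) {
    cfg <- list(nTissues = nTissues, nStages = nStages,
                nTimepointsPerStage = nTimepointsPerStage,
                nReplicates = nReplicates, nGenes = nGenes,
                baselineLog2Mean = baselineLog2Mean,
                baselineLog2Sd = baselineLog2Sd,
                nSpecificPerTissue = nSpecificPerTissue,
                tissueEffectLog2 = tissueEffectLog2,
                nSpecificPerStage = nSpecificPerStage,
                stageEffectLog2 = stageEffectLog2,
                nTrajectoryGenes = nTrajectoryGenes,
                nArchetypes = nArchetypes, noiseSd = noiseSd, seed = seed)
    counts <- c("nTissues", "nStages", "nTimepointsPerStage", "nReplicates",
                "nGenes", "nArchetypes")
    for (f in counts)
        if (cfg[[f]] < 1) stop("config error: '", f, "' must be >= 1")
    for (f in c("nSpecificPerTissue", "nSpecificPerStage", "nTrajectoryGenes"))
        if (cfg[[f]] < 0) stop("config error: '", f, "' must be >= 0")
    for (f in c("tissueEffectLog2", "stageEffectLog2", "noiseSd",
                "baselineLog2Sd"))
        if (cfg[[f]] < 0) stop("config error: '", f, "' must be >= 0")
    budget <- nSpecificPerTissue * nTissues + nSpecificPerStage * nStages +
        nTrajectoryGenes
    if (budget > nGenes)
        stop("config error: planted gene budget (", budget,
             ") exceeds nGenes (", nGenes, ")")
    structure(cfg, class = "AtlasSimConfig")
}

## Fixed archetype trajectory shapes evaluated at nStages points, each scaled
## to unit amplitude (min 0, max 1). Archetypes beyond the four canonical
## shapes are raised-cosine curves of increasing frequency.
archetypeCurves <- function(nStages, nArchetypes) {
    t <- if (nStages == 1L) 0.5 else seq(0, 1, length.out = nStages)
    unit <- function(v) {
        r <- max(v) - min(v)
        if (r == 0) rep(0, length(v)) else (v - min(v)) / r
    }
    shape <- function(a) {
        switch(min(a, 5L),
            t,                              # monotone up
            1 - t,                          # monotone down
            exp(-((t - 0.5) / 0.25)^2),     # single peak
            1 - exp(-((t - 0.5) / 0.25)^2), # single dip
            0.5 * (1 + cos((a - 3) * pi * t)))
    }
    curves <- vapply(seq_len(nArchetypes), function(a) unit(shape(a)),
                     numeric(nStages))
    t(curves)  # nArchetypes x nStages
}

#' Simulate a multi-tissue developmental expression atlas
#'
#' Generates a TPM atlas with known planted structure. On the log2 scale each
#' gene/sample value is baseline + tissue effect (planted tissue-specific
#' genes, in their target tissue only) + stage effect (planted stage-specific
#' genes, at their target stage in all tissues) + archetype curve value
#' (trajectory genes) + Gaussian noise. Values are exponentiated and every
#' sample column is rescaled to sum to 1e6, so the output is a proper TPM
#' matrix.
#'
#' @param cfg an [atlasSimConfig()] object.
#' @return A list with elements \code{atlas} (an
#'   [ExpressionAtlas-class]) and \code{truth}, a list recording the planted
#'   tissue-specific genes per tissue, stage-specific genes per stage, and
#'   trajectory archetype per gene.
#' @examples
#' sim <- simulateAtlas(atlasSimConfig(nTissues = 3, nStages = 2,
#'                                     nGenes = 60, nSpecificPerTissue = 5,
#'                                     nSpecificPerStage = 5,
#'                                     nTrajectoryGenes = 8, seed = 42))
#' sim$atlas
#' @export
simulateAtlas <- function(cfg) {
    stopifnot(inherits(cfg, "AtlasSimConfig"))
    genes <- sprintf("gene%04d", seq_len(cfg$nGenes))
    tissues <- sprintf("tissue%02d", seq_len(cfg$nTissues))
    stages <- sprintf("stage%d", seq_len(cfg$nStages))
    design <- expand.grid(rep = seq_len(cfg$nReplicates),
                          tp = seq_len(cfg$nTimepointsPerStage),
                          stage = seq_len(cfg$nStages),
                          tissue = seq_len(cfg$nTissues))
    sampleId <- sprintf("T%02d_S%d_P%d_R%d", design$tissue, design$stage,
                        design$tp, design$rep)
    nS <- nrow(design)

    ## partition planted genes: tissue-specific block, stage-specific block,
    ## trajectory block, then unplanted background
    idx <- 0L
    take <- function(n) {
        out <- seq_len(n) + idx
        idx <<- idx + n
        out
    }
    tsGenes <- lapply(seq_len(cfg$nTissues),
                      function(t) genes[take(cfg$nSpecificPerTissue)])
    names(tsGenes) <- tissues
    ssGenes <- lapply(seq_len(cfg$nStages),
                      function(s) genes[take(cfg$nSpecificPerStage)])
    names(ssGenes) <- stages
    trajIdx <- take(cfg$nTrajectoryGenes)
    archetype <- if (cfg$nTrajectoryGenes)
        rep_len(seq_len(cfg$nArchetypes), cfg$nTrajectoryGenes) else integer()
    names(archetype) <- genes[trajIdx]
    curves <- archetypeCurves(cfg$nStages, cfg$nArchetypes)

    mat <- withSeed(cfg$seed, {
        base <- stats::rnorm(cfg$nGenes, cfg$baselineLog2Mean,
                             cfg$baselineLog2Sd)
        log2mat <- matrix(base, cfg$nGenes, nS)
        for (t in seq_len(cfg$nTissues)) {
            gi <- match(tsGenes[[t]], genes)
            si <- which(design$tissue == t)
            log2mat[gi, si] <- log2mat[gi, si] + cfg$tissueEffectLog2
        }
        for (s in seq_len(cfg$nStages)) {
            gi <- match(ssGenes[[s]], genes)
            si <- which(design$stage == s)
            log2mat[gi, si] <- log2mat[gi, si] + cfg$stageEffectLog2
        }
        if (length(trajIdx))
            log2mat[trajIdx, ] <- log2mat[trajIdx, ] +
                curves[archetype, design$stage, drop = FALSE]
        log2mat <- log2mat +
            matrix(stats::rnorm(cfg$nGenes * nS, 0, cfg$noiseSd),
                   cfg$nGenes, nS)
        2^log2mat
    })
    mat <- sweep(mat, 2, colSums(mat), "/") * 1e6
    dimnames(mat) <- list(genes, sampleId)

    meta <- data.frame(sample_id = sampleId,
                       tissue = tissues[design$tissue],
                       stage = stages[design$stage],
                       timepoint = sprintf("tp%d", design$tp))
    atlas <- ExpressionAtlas(mat, meta, stageLevels = stages)
    truth <- list(tissueSpecific = tsGenes, stageSpecific = ssGenes,
                  trajectoryArchetype = archetype)
    list(atlas = atlas, truth = truth)
}

#' Configuration for the synthetic genome / GWAS generator
#'
#' @param nChromosomes chromosomes over which genes are tiled.
#' @param geneLength,intergenicGap bp length of every gene body and of the
#'   gap between consecutive genes; the tiling is deterministic so window
#'   overlaps are analytically predictable.
#' @param nSnps SNPs placed uniformly over the covered genome.
#' @param backgroundEffectSd SD of the Gaussian SNP effect for background
#'   SNPs.
#' @param enrichedEffectSd SD for SNPs falling in the cis-windows of
#'   \code{enrichedGeneSet}; equal to \code{backgroundEffectSd} gives a null
#'   GWAS.
#' @param enrichedGeneSet a [GeneSet-class] naming the genes whose windows
#'   carry inflated effects, or \code{NULL} for a fully null GWAS.
#' @param window bp flank defining those windows (default 20000, the
#'   cis-regulatory flank used throughout the package).
#' @param seed RNG seed.
#' @return A validated list of class \code{"GenomeSimConfig"}.
#' @export
genomeSimConfig <- function(nChromosomes = 3, geneLength = 10000,
                            intergenicGap = 30000, nSnps = 20000,
                            backgroundEffectSd = 0.1,
                            enrichedEffectSd = 0.1,
                            enrichedGeneSet = NULL, window = 20000,
                            seed = 1) {
    if (nChromosomes < 1) stop("config error: 'nChromosomes' must be >= 1")
    if (geneLength <= 0) stop("config error: 'geneLength' must be > 0")
    if (intergenicGap < 0) stop("config error: 'intergenicGap' must be >= 0")
    if (nSnps < 0) stop("config error: 'nSnps' must be >= 0")
    if (backgroundEffectSd < 0 || enrichedEffectSd < 0)
        stop("config error: effect SDs must be >= 0")
    if (window < 0) stop("config error: 'window' must be >= 0")
    structure(list(nChromosomes = nChromosomes, geneLength = geneLength,
                   intergenicGap = intergenicGap, nSnps = nSnps,
                   backgroundEffectSd = backgroundEffectSd,
                   enrichedEffectSd = enrichedEffectSd,
                   enrichedGeneSet = enrichedGeneSet, window = window,
                   seed = seed),
              class = "GenomeSimConfig")
}

#' Simulate a gene annotation and GWAS summary statistics
#'
#' Tiles the supplied genes across chromosomes at fixed spacing (1-based,
#' inclusive coordinates; strands alternate + and -), places SNPs uniformly
#' over the covered genome, and draws each SNP effect from
#' Normal(0, backgroundEffectSd^2) — except SNPs inside the cis-windows of
#' the configured enriched gene set, which draw from
#' Normal(0, enrichedEffectSd^2).
#'
#' @param cfg a [genomeSimConfig()] object.
#' @param genes character vector of gene ids to place (non-empty).
#' @return A list with \code{annotation} (a named
#'   \link[GenomicRanges]{GRanges}), \code{gwas} (data.frame: snp_id, chrom,
#'   pos, beta) and \code{truth} (per-SNP regime, \code{"background"} or
#'   \code{"enriched"}).
#' @export
simulateGenomeGwas <- function(cfg, genes) {
    stopifnot(inherits(cfg, "GenomeSimConfig"))
    genes <- as.character(genes)
    if (!length(genes)) stop("'genes' must be non-empty")
    if (!is.null(cfg$enrichedGeneSet)) {
        unknown <- setdiff(geneIds(cfg$enrichedGeneSet), genes)
        if (length(unknown))
            stop("enriched gene set contains unknown gene ids: ",
                 paste(unknown, collapse = ", "))
    }
    n <- length(genes)
    perChrom <- ceiling(n / cfg$nChromosomes)
    chromIdx <- rep(seq_len(cfg$nChromosomes), each = perChrom)[seq_len(n)]
    within <- sequence(tabulate(chromIdx, cfg$nChromosomes))
    pitch <- cfg$geneLength + cfg$intergenicGap
    start <- (within - 1) * pitch + 1
    end <- start + cfg$geneLength - 1
    chromNames <- sprintf("chr%d", seq_len(cfg$nChromosomes))
    ann <- GenomicRanges::GRanges(
        seqnames = chromNames[chromIdx],
        ranges = IRanges::IRanges(start = start, end = end),
        strand = rep_len(c("+", "-"), n))
    names(ann) <- genes

    chromLen <- vapply(seq_len(cfg$nChromosomes), function(c) {
        hit <- chromIdx == c
        if (any(hit)) max(end[hit]) + cfg$intergenicGap else 0
    }, numeric(1))

    if (cfg$nSnps == 0) {
        gwas <- data.frame(snp_id = character(), chrom = character(),
                           pos = integer(), beta = numeric())
        return(list(annotation = ann, gwas = gwas,
                    truth = list(snpRegime = character())))
    }

    out <- withSeed(cfg$seed, {
        u <- stats::runif(cfg$nSnps, 0, sum(chromLen))
        cum <- cumsum(chromLen)
        sChrom <- findInterval(u, cum) + 1L
        pos <- pmax(1L, as.integer(ceiling(u - c(0, cum)[sChrom])))
        regime <- rep("background", cfg$nSnps)
        if (!is.null(cfg$enrichedGeneSet)) {
            gi <- match(geneIds(cfg$enrichedGeneSet), genes)
            winStart <- pmax(1, start[gi] - cfg$window)
            winEnd <- end[gi] + cfg$window
            winChrom <- chromIdx[gi]
            for (j in seq_along(gi)) {
                hit <- sChrom == winChrom[j] & pos >= winStart[j] &
                    pos <= winEnd[j]
                regime[hit] <- "enriched"
            }
        }
        sd <- ifelse(regime == "enriched", cfg$enrichedEffectSd,
                     cfg$backgroundEffectSd)
        beta <- stats::rnorm(cfg$nSnps, 0, sd)
        list(chrom = sChrom, pos = pos, beta = beta, regime = regime)
    })
    snpId <- sprintf("snp%06d", seq_len(cfg$nSnps))
    gwas <- data.frame(snp_id = snpId, chrom = chromNames[out$chrom],
                       pos = out$pos, beta = out$beta)
    names(out$regime) <- snpId
    list(annotation = ann, gwas = gwas,
         truth = list(snpRegime = out$regime))
}

#' Write a simulated dataset to disk
#'
#' Emits the standard plain-text artifacts for a simulation: expression TSV,
#' sample-metadata TSV, gene-feature GFF3, GWAS summary TSV, and a truth JSON
#' recording every planting. Fixed seeds give byte-identical files.
#'
#' @param sim result of [simulateAtlas()].
#' @param genomeSim result of [simulateGenomeGwas()], or \code{NULL} to skip
#'   the genome artifacts.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
writeSimulation <- function(sim, genomeSim = NULL, dir = ".") {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(expression = file.path(dir, "expression.tsv"),
               samples = file.path(dir, "samples.tsv"),
               truth = file.path(dir, "truth.json"))
    writeExpressionAtlas(sim$atlas, paths[["expression"]], paths[["samples"]])
    truth <- sim$truth
    truth$trajectoryArchetype <- as.list(truth$trajectoryArchetype)
    if (!is.null(genomeSim)) {
        paths <- c(paths, annotation = file.path(dir, "genes.gff3"),
                   gwas = file.path(dir, "gwas.tsv"))
        writeGeneAnnotation(genomeSim$annotation, paths[["annotation"]])
        writeGwasSummary(genomeSim$gwas, paths[["gwas"]])
        truth$snpRegime <- as.list(genomeSim$truth$snpRegime)
    }
    jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(paths)
}
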