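# Report-emitting workflows chaining the pipeline stages.  Reports are
# deterministic: headers echo the package version, the configuration and
# the seed (and the isotope-table version where relevant), and contain
# no timestamps, so identical configurations give byte-identical files.

.reportHeader <- function(config, extra = character()) {
  cfg <- vapply(names(config), function(k) {
    v <- config[[k]]
    paste0(k, "=", paste(format(v, trim = TRUE), collapse = ","))
  }, character(1))
  c(paste0("# swfscreen v", as.character(packageVersion("swfscreen"))),
    paste0("# ", cfg), extra)
}

.writeTsv <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the end-to-end amplicon screen
#'
#' Chains primer design, in-silico PCR, translation of each amplicon in
#' the frame anchored by the forward primer site, and signature-motif
#' family classification, over one or more primer pairs (by default the
#' broad AT pair AT1F/AT3R2 and the swf-specific pair
#' SWF_ATF/SWF_ATR).  Emits `amplicons.fasta`, `amplicons.tsv`,
#' `classification.tsv` and `summary.tsv` into `outDir`.
#'
#' @param contigs a [Biostrings::DNAStringSet] or path to a contig
#'   FASTA.
#' @param outDir output directory (created if missing).
#' @param primerPairs named list of primer pairs (each a
#'   `list(fwd =, rev =)` of [DegeneratePrimer-class]); default both
#'   built-in pairs.
#' @param maxMismatch,clampLen,minLen,maxLen in-silico PCR settings,
#'   see [amplify()].
#' @param specs motif specs for classification.
#' @return Invisibly, a list with `amplicons`, `calls` and `summary`
#'   data.frames.
#' @export
runScreen <- function(contigs, outDir,
                      primerPairs = list(AT = atPrimerPair(),
                                         SWF = swfPrimerPair()),
                      maxMismatch = 2L, clampLen = 3L, minLen = 50L,
                      maxLen = 2000L, specs = swfMotifSpecs()) {
  if (is.character(contigs)) contigs <- readFasta(contigs, "DNA")
  if (length(contigs) == 0L) stop("no contigs supplied")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  config <- list(
    primer_pairs = paste(vapply(primerPairs, function(p)
      paste(primerName(p$fwd), primerName(p$rev), sep = "/"),
      character(1)), collapse = ";"),
    max_mismatch = maxMismatch, clamp_len = clampLen,
    min_len = minLen, max_len = maxLen)

  allAmps <- list()
  for (pairName in names(primerPairs)) {
    pair <- primerPairs[[pairName]]
    amps <- amplify(contigs, pair$fwd, pair$rev, maxMismatch, clampLen,
                    minLen, maxLen)
    if (nrow(amps)) {
      amps <- cbind(data.frame(primer_pair = paste(
        primerName(pair$fwd), primerName(pair$rev), sep = "/")), amps)
      allAmps[[pairName]] <- amps
    }
  }
  amplicons <- if (length(allAmps)) do.call(rbind, allAmps) else
    data.frame(primer_pair = character(), contig_id = character(),
               strand = character(), start = integer(), end = integer(),
               length = integer(), fwd_mismatches = integer(),
               rev_mismatches = integer(), sequence = character())
  rownames(amplicons) <- NULL

  # translate each amplicon in the frame anchored by the forward primer
  # (the amplicon starts at the forward-primer window)
  proteins <- vapply(amplicons$sequence, function(s)
    as.character(translateFrame(s, 1L, "+")), character(1),
    USE.NAMES = FALSE)
  ids <- sprintf("%s_%d_%d%s", amplicons$contig_id, amplicons$start,
                 amplicons$end, amplicons$strand)
  calls <- if (nrow(amplicons))
    classifyProteins(setNames(proteins, ids), specs)
  else classifyProteins(setNames(character(), character()), specs)
  if (nrow(amplicons)) calls <- cbind(calls,
    amplicons[, c("primer_pair", "length")])

  famCounts <- table(factor(calls$label,
    levels = c("swf", "cis-AT-like", "radical-SAM", "unclassified")))
  summary <- data.frame(family = names(famCounts),
                        n_amplicons = as.integer(famCounts))
  lenDist <- if (nrow(amplicons))
    paste(sort(unique(amplicons$length)), collapse = ",") else ""

  hdr <- .reportHeader(config)
  writeAmplicons(amplicons, file.path(outDir, "amplicons.tsv"),
                 file.path(outDir, "amplicons.fasta"), hdr)
  .writeTsv(calls, file.path(outDir, "classification.tsv"), hdr)
  .writeTsv(summary, file.path(outDir, "summary.tsv"),
            c(hdr, paste0("# amplicon_lengths=", lenDist)))
  invisible(list(amplicons = amplicons, calls = calls, summary = summary))
}

#' Run the proteoform mass-spectrometry report
#'
#' From the apo-protein formula, computes the holo formulas under both
#' phosphopantetheinylation variants (radical, nominal +339;
#' even-electron, nominal +340), monoisotopic masses, the charge ladder
#' of monoisotopic and most-intense peaks, the disulfide dimer, and
#' optionally matches a supplied peak list (columns `mz`, `intensity`)
#' with ppm errors.  Writes `mass_report.tsv`, `charge_ladder.tsv` and,
#' when peaks are supplied, `peak_matches.tsv`.
#'
#' @param apoFormula apo-protein formula string or
#'   [ChemicalFormula-class].
#' @param outDir output directory.
#' @param peakList optional `data.frame` with an `mz` column (or a
#'   numeric vector), or a path to a two-column whitespace-delimited
#'   file `mz intensity`.
#' @param zRange charge states for the ladder.
#' @param pruneThreshold isotope-pattern pruning threshold.
#' @return Invisibly, a list with `formulas`, `ladders` and `matches`.
#' @export
runMass <- function(apoFormula = "C449H704N134O140S3", outDir,
                    peakList = NULL, zRange = 1:10,
                    pruneThreshold = 1e-10) {
  apo <- .asFormula(apoFormula)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  holoRad <- ppantAdduct(apo, "radical")
  holoEven <- ppantAdduct(apo, "even_electron")
  dimer <- disulfideDimer(holoRad)
  forms <- list(apo = apo, holo_radical = holoRad,
                holo_even_electron = holoEven, holo_disulfide_dimer = dimer)
  formulas <- data.frame(
    proteoform = names(forms),
    formula = vapply(forms, formulaString, character(1)),
    monoisotopic_mass = vapply(forms, monoisotopicMass, numeric(1)),
    nominal_mass = vapply(forms, nominalMass, integer(1)))
  formulas$delta_vs_apo <- formulas$monoisotopic_mass -
    formulas$monoisotopic_mass[1L]
  ladders <- do.call(rbind, lapply(names(forms), function(nm) {
    cbind(data.frame(proteoform = nm),
          chargeLadder(forms[[nm]], zRange, pruneThreshold))
  }))
  matches <- NULL
  if (!is.null(peakList)) {
    if (is.character(peakList))
      peakList <- read.table(peakList, header = FALSE,
                             col.names = c("mz", "intensity"))
    perForm <- lapply(names(forms)[1:2], function(nm) {
      cbind(data.frame(proteoform = nm),
            matchPeaks(peakList, forms[[nm]], zRange, pruneThreshold))
    })
    matches <- do.call(rbind, perForm)
  }
  config <- list(apo_formula = formulaString(apo),
                 prune_threshold = pruneThreshold,
                 z_range = paste(range(zRange), collapse = "-"))
  hdr <- .reportHeader(config,
    paste0("# isotope_table=", isotopeTableVersion()))
  .writeTsv(formulas, file.path(outDir, "mass_report.tsv"), hdr)
  .writeTsv(ladders, file.path(outDir, "charge_ladder.tsv"), hdr)
  if (!is.null(matches))
    .writeTsv(matches, file.path(outDir, "peak_matches.tsv"), hdr)
  invisible(list(formulas = formulas, ladders = ladders, matches = matches))
}

#' Run the distance phylogeny workflow
#'
#' p-distance matrix, neighbour-joining tree, bootstrap bipartition
#' support, optional outgroup rooting and optional support-cutoff
#' condensation.  Writes `tree.nwk` (supports as internal node labels),
#' `condensed.nwk` (when a cutoff is given), `distances.tsv` and
#' `phylo_report.tsv`.
#'
#' @param aln aligned proteins: [Biostrings::AAStringSet], named
#'   character vector, or path to an aligned FASTA.
#' @param outDir output directory.
#' @param outgroup optional tip label to root on.
#' @param nReplicates bootstrap replicates.
#' @param seed bootstrap seed (echoed in the report).
#' @param cutoff optional condensation support cutoff in percent.
#' @param correction distance correction, see [pDistance()].
#' @return Invisibly, a list with `distances`, `tree` and `condensed`.
#' @export
runPhylo <- function(aln, outDir, outgroup = NULL, nReplicates = 100L,
                     seed = 1L, cutoff = NULL, correction = "none") {
  if (is.character(aln) && length(aln) == 1L && file.exists(aln))
    aln <- readFasta(aln, "AA")
  m <- .alnMatrix(aln)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(outgroup) && !outgroup %in% rownames(m))
    stop("outgroup label not found in alignment: '", outgroup, "'")
  D <- pDistance(m, correction = correction)
  tr <- bootstrapSupport(m, nReplicates = nReplicates, seed = seed,
                         correction = correction)
  if (!is.null(outgroup)) tr <- rootWithOutgroup(tr, outgroup)
  cond <- if (!is.null(cutoff)) condenseTree(tr, cutoff) else NULL
  config <- list(n_taxa = nrow(m), n_columns = ncol(m),
                 correction = correction, n_replicates = nReplicates,
                 seed = seed,
                 outgroup = if (is.null(outgroup)) "none" else outgroup,
                 condense_cutoff = if (is.null(cutoff)) "none" else cutoff)
  hdr <- .reportHeader(config)
  .writeTsv(data.frame(taxon = rownames(D), round(D, 6)),
            file.path(outDir, "distances.tsv"), hdr)
  writeNewick(tr, file.path(outDir, "tree.nwk"))
  if (!is.null(cond)) writeNewick(cond, file.path(outDir, "condensed.nwk"))
  .writeTsv(data.frame(setting = names(config),
                       value = vapply(config, function(v)
                         paste(format(v, trim = TRUE), collapse = ","),
                         character(1))),
            file.path(outDir, "phylo_report.tsv"), hdr)
  invisible(list(distances = D, tree = tr, condensed = cond))
}
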