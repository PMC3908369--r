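# Signature-motif scanning and PKS family classification.
#
# The discriminating observations: in swf-type ketosynthase domains the
# second Q of the canonical DPQQR motif is replaced by I or V (as in
# animal FAS I), and the condensation motif HGTGT of cis-AT PKSs reads
# HATGT.  In the acyltransferase domain IAFH points to malonyl-CoA
# loading, the active-site motif reads GHS-x-GE with an unusual Ser at
# the variable position, and QCALVEL (variable at its first and last
# residues) is a unique swf signature.  Radical SAM enzymes carry the
# cysteine triad C-x(3)-C-x(2)-C.

#' Default signature-motif specifications
#'
#' Each spec is a list with fields `name`, `pattern` (amino-acid pattern;
#' `[..]` = allowed set, `.` = any residue), `type` and a family evidence
#' tag.  Types: `"variant"` (one position separates the canonical from
#' the swf variant), `"presence"` (matched or absent), `"record"` (the
#' residue at `record_pos` is reported verbatim, not classified),
#' `"edge"` (exact match preferred; substitutions tolerated at the
#' `edge_tolerance` leading/trailing positions).
#'
#' @return A named list of motif specs, usable with [scanMotifs()].
#' @export
swfMotifSpecs <- function() {
  list(
    DPQQR = list(name = "DPQQR", pattern = "DPQ[QIV]R", type = "variant",
                 variant_pos = 4L, canonical = "Q", swf = c("I", "V"),
                 tag = "KS_active_site"),
    HGTGT = list(name = "HGTGT", pattern = "H[GA]TGT", type = "variant",
                 variant_pos = 2L, canonical = "G", swf = "A",
                 tag = "KS_condensation"),
    IAFH = list(name = "IAFH", pattern = "IAFH", type = "presence",
                tag = "AT_malonyl_specificity"),
    GHSxGE = list(name = "GHSxGE", pattern = "GHS.GE", type = "record",
                  record_pos = 4L, tag = "AT_active_site"),
    QCALVEL = list(name = "QCALVEL", pattern = "QCALVEL", type = "edge",
                   edge_tolerance = 1L, tag = "swf_AT_signature"),
    CxxxCxxC = list(name = "CxxxCxxC", pattern = "C...C..C",
                    type = "presence", tag = "radical_SAM")
  )
}

# Relaxed regex for an edge-tolerant motif: the first/last edge_tolerance
# literal positions become wildcards.
.edgeRelaxedPattern <- function(pattern, tol) {
  ch <- .chars(pattern)
  n <- length(ch)
  if (tol > 0L) {
    ch[seq_len(min(tol, n))] <- "."
    ch[(n - min(tol, n) + 1L):n] <- "."
  }
  paste(ch, collapse = "")
}

#' Scan a protein for signature motifs
#'
#' For each motif spec, reports absence or the matched variant class and
#' its 1-based position.  Edge-tolerant motifs (QCALVEL) match exactly
#' when possible; otherwise substitutions are accepted at the first and
#' last `edge_tolerance` positions only, and the hit is reported as
#' `swf-variant`.
#'
#' @param protein character string, [Biostrings::AAString], or a
#'   length-one named vector.
#' @param specs motif specs, default [swfMotifSpecs()].
#' @return Named list (one element per motif) of lists with fields
#'   `status` (`"absent"`, `"canonical"` or `"swf-variant"`), `position`
#'   (1-based start, `NA` when absent), `match` (matched substring) and,
#'   for `record` motifs, `residue`.
#' @export
scanMotifs <- function(protein, specs = swfMotifSpecs()) {
  p <- toupper(as.character(protein))
  if (nchar(p) == 0L) stop("empty protein sequence")
  out <- lapply(specs, function(sp) {
    hit <- regexpr(sp$pattern, p)
    if (hit > 0L) {
      m <- regmatches(p, hit)
      pos <- as.integer(hit)
      status <- switch(sp$type,
        presence = "canonical",
        record = "canonical",
        edge = "canonical",
        variant = {
          v <- substr(m, sp$variant_pos, sp$variant_pos)
          if (v %in% sp$swf) "swf-variant" else "canonical"
        })
      res <- list(status = status, position = pos, match = m)
      if (sp$type == "record")
        res$residue <- substr(m, sp$record_pos, sp$record_pos)
      return(res)
    }
    if (identical(sp$type, "edge") && sp$edge_tolerance > 0L) {
      relaxed <- .edgeRelaxedPattern(sp$pattern, sp$edge_tolerance)
      hit2 <- regexpr(relaxed, p)
      if (hit2 > 0L) {
        return(list(status = "swf-variant", position = as.integer(hit2),
                    match = regmatches(p, hit2)))
      }
    }
    list(status = "absent", position = NA_integer_, match = NA_character_)
  })
  names(out) <- names(specs)
  out
}

#' Classify a protein's family from its motif evidence
#'
#' Deterministic rule table, applied in order:
#' 1. QCALVEL present (exact or edge-varied) -> `swf` (the motif is a
#'    unique swf acyltransferase signature, so it dominates conflicting
#'    evidence);
#' 2. both DPQ\[IV\]R and HATGT present -> `swf`;
#' 3. intact DPQQR and HGTGT present and QCALVEL absent -> `cis-AT-like`;
#' 4. C-x(3)-C-x(2)-C present with no KS/AT evidence -> `radical-SAM`;
#' 5. otherwise `unclassified`.
#'
#' @param evidence evidence map from [scanMotifs()].
#' @return List with fields `label`, `rule` (index of the firing rule)
#'   and `rationale`.
#' @examples
#' classifyFamily(scanMotifs("AAAQCALVELAAA"))$label  # "swf"
#' @export
classifyFamily <- function(evidence) {
  st <- function(m) if (m %in% names(evidence)) evidence[[m]]$status
                    else "absent"
  qc <- st("QCALVEL"); dp <- st("DPQQR"); hg <- st("HGTGT")
  ia <- st("IAFH"); gh <- st("GHSxGE"); cx <- st("CxxxCxxC")
  if (qc != "absent") {
    return(list(label = "swf", rule = 1L,
                rationale = "QCALVEL swf signature present"))
  }
  if (dp == "swf-variant" && hg == "swf-variant") {
    return(list(label = "swf", rule = 2L,
                rationale = "swf KS variants DPQ[IV]R and HATGT both present"))
  }
  if (dp == "canonical" && hg == "canonical") {
    return(list(label = "cis-AT-like", rule = 3L,
                rationale = "intact DPQQR and HGTGT, no QCALVEL"))
  }
  ksatAbsent <- dp == "absent" && hg == "absent" && ia == "absent" &&
    gh == "absent"
  if (cx != "absent" && ksatAbsent) {
    return(list(label = "radical-SAM", rule = 4L,
                rationale = "cysteine triad C-x(3)-C-x(2)-C, no KS/AT evidence"))
  }
  list(label = "unclassified", rule = 5L,
       rationale = "no rule matched the evidence")
}

#' Classify a set of proteins and tabulate the evidence
#'
#' @param proteins [Biostrings::AAStringSet] or named character vector.
#' @param specs motif specs, default [swfMotifSpecs()].
#' @return `data.frame` with one row per protein: `sequence_id`, one
#'   status column per motif, `label`, `rationale`.
#' @export
classifyProteins <- function(proteins, specs = swfMotifSpecs()) {
  nms <- names(proteins)
  seqs <- as.character(proteins)
  if (is.null(names(seqs))) names(seqs) <- nms
  if (!length(seqs)) {
    cols <- c("sequence_id", names(specs), "label", "rationale")
    out <- as.data.frame(setNames(rep(list(character()), length(cols)),
                                  cols), stringsAsFactors = FALSE)
    return(out)
  }
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("seq%02d", seq_along(seqs))
  rows <- lapply(seq_along(seqs), function(i) {
    ev <- scanMotifs(seqs[[i]], specs)
    call <- classifyFamily(ev)
    stat <- vapply(ev, function(e) e$status, character(1))
    df <- as.data.frame(as.list(stat), stringsAsFactors = FALSE)
    cbind(data.frame(sequence_id = ids[[i]], stringsAsFactors = FALSE),
          df, data.frame(label = call$label, rationale = call$rationale,
                         stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}
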