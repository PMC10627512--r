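#' Classify a Gly-rich-loop phosphosite triplet into a motif group
#'
#' HipT-family Ser/Thr kinases carry two candidate phosphorylation sites in
#' the Gly-rich loop, separated by one small aliphatic residue (Psi = Ile,
#' Leu or Val).  The three-residue window at these sites defines the motif
#' groups used to organize the family: `SPsiS` (two serines, e.g. the
#' Ser57/Ser59 pair of the E. coli kinase), `(S/T)PsiT`, `(S/T)PsiP`,
#' `SPsiQ`, `PsiPsiT`, and `other`.  Precedence is SPsiS, (S/T)PsiT,
#' (S/T)PsiP, SPsiQ, PsiPsiT; a non-aliphatic center residue always maps to
#' `other`.  The rules are total: every triplet maps to exactly one group.
#'
#' @param triplet character vector of 3-letter amino-acid windows
#'   (1-letter code), e.g. `"SIS"`.
#' @return Character vector of group labels.
#' @export
classify_motif <- function(triplet) {
  triplet <- toupper(triplet)
  if (any(nchar(triplet) != 3L)) stop("triplets must have length 3")
  valid <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  amb <- c("X", "B", "Z", "J", "U", "O")
  mat <- do.call(rbind, strsplit(triplet, ""))
  bad <- !(mat %in% c(valid, amb))
  if (any(bad))
    stop("invalid residue letter(s): ",
         paste(unique(mat[bad]), collapse = ", "))
  if (any(mat %in% amb))
    warning("ambiguity letters (X/B/Z/...) classified as 'other'")
  psi <- c("I", "L", "V")
  f1 <- mat[, 1]; ctr <- mat[, 2]; f3 <- mat[, 3]
  out <- rep("other", length(triplet))
  aliph <- ctr %in% psi
  st1 <- f1 %in% c("S", "T")
  out[aliph & f1 == "S" & f3 == "S"] <- "SPsiS"
  sel <- aliph & out == "other" & st1 & f3 == "T"
  out[sel] <- "(S/T)PsiT"
  sel <- aliph & out == "other" & st1 & f3 == "P"
  out[sel] <- "(S/T)PsiP"
  sel <- aliph & out == "other" & f1 == "S" & f3 == "Q"
  out[sel] <- "SPsiQ"
  sel <- aliph & out == "other" & f1 %in% psi & f3 == "T"
  out[sel] <- "PsiPsiT"
  out
}

#' Motif group labels, in precedence order
#' @return Character vector of the six labels.
#' @export
motif_groups <- function() {
  c("SPsiS", "(S/T)PsiT", "(S/T)PsiP", "SPsiQ", "PsiPsiT", "other")
}

## locate the phosphosite window in a full sequence: explicit coordinates
## or first regex match of an anchor pattern
locate_window <- function(seq, window) {
  if (is.numeric(window)) {
    if (window[1] < 1 || window[1] + 2 > nchar(seq)) return(NA_integer_)
    return(as.integer(window[1]))
  }
  m <- regexpr(window, seq, perl = TRUE)
  if (m == -1L) return(NA_integer_)
  as.integer(m)
}

#' Classify loop sequences from a FASTA file
#'
#' Reads (aligned or unaligned) sequences and classifies the phosphosite
#' triplet of each record.  The window is located either by explicit start
#' coordinate or by the first match of an anchor regular expression
#' (default: a Ser/Thr followed by an aliphatic residue,
#' `"[ST][ILV][A-Z]"`, the two-site spacing of the family).  Records whose
#' window cannot be located are flagged, not dropped.
#'
#' @param fasta path to a FASTA file, or a named character vector of
#'   sequences.
#' @param window `"auto"` (use `anchor`), a regular expression, or an
#'   integer start position of the 3-residue window.
#' @param anchor anchor pattern used when `window = "auto"`.
#' @return data.frame with columns `id`, `triplet`, `group`, `flagged`.
#' @export
classify_fasta <- function(fasta, window = "auto",
                           anchor = "[ST][ILV][A-Z]") {
  if (length(fasta) == 1L && !grepl("[\n>]", fasta) && file.exists(fasta)) {
    fa <- bio3d::read.fasta(fasta)
    ids <- fa$id
    seqs <- apply(fa$ali, 1, function(r) paste(r[r != "-"], collapse = ""))
  } else {
    seqs <- unname(fasta)
    ids <- names(fasta)
    if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  }
  if (length(seqs) == 0L) stop("no sequences in input")
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(seqs)
  pat <- if (identical(window, "auto")) anchor else window
  starts <- vapply(seqs, locate_window, integer(1), window = pat)
  triplet <- ifelse(is.na(starts), NA_character_,
                    substr(seqs, starts, starts + 2L))
  group <- rep(NA_character_, length(seqs))
  ok <- !is.na(triplet)
  if (any(ok)) group[ok] <- classify_motif(triplet[ok])
  data.frame(id = ids, triplet = triplet, group = group,
             flagged = !ok, row.names = NULL)
}

#' Per-position residue frequencies over the classified windows
#'
#' Tabulates residue counts and frequencies at each position of the
#' 3-residue phosphosite window, the input for consensus-motif or logo
#' construction.  Counts at each position sum to the number of classified
#' rows; frequencies sum to 1.
#'
#' @param table output of [classify_fasta] (flagged rows are skipped), or a
#'   character vector of triplets.
#' @return List with matrices `counts` and `freq` (20 residues x 3
#'   positions) and `n` (number of sequences tabulated).
#' @export
consensus_counts <- function(table) {
  triplets <- if (is.data.frame(table)) {
    table$triplet[!table$flagged & !is.na(table$triplet)]
  } else as.character(table)
  if (length(triplets) == 0L) stop("no classified rows to tabulate")
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  mat <- do.call(rbind, strsplit(toupper(triplets), ""))
  counts <- vapply(1:3, function(j)
    base::table(factor(mat[, j], levels = aa)), numeric(length(aa)))
  dimnames(counts) <- list(aa, paste0("pos", 1:3))
  list(counts = counts, freq = sweep(counts, 2, colSums(counts), "/"),
       n = length(triplets))
}
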