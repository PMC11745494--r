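# Internal helpers shared across modules.

#' @importFrom rlang %||% .data
#' @importFrom stats cor cor.test density p.adjust pchisq rbinom rmultinom
#'   rlnorm rnbinom rpois runif setNames t.test var wilcox.test
#' @importFrom utils head
NULL

# clonotype identity key: CDR-H3 nucleotide sequence + V gene + J gene
# (isotype deliberately excluded)
clonotype_key <- function(cdr3_nt, v_gene, j_gene) {
  paste(cdr3_nt, v_gene, j_gene, sep = "|")
}

# standard genetic code; stop codons translate to "*"
GENETIC_CODE_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

split_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# translate an in-frame nucleotide string; NA when length is not a multiple
# of 3 or when a codon contains an ambiguous base
translate_nt <- function(seq) {
  vapply(seq, function(s) {
    if (is.na(s) || nchar(s) %% 3L != 0L || nchar(s) == 0L) return(NA_character_)
    aa <- GENETIC_CODE_TABLE[split_codons(s)]
    if (anyNA(aa)) return(NA_character_)
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# pairwise identity of two sequences on an equal-length trim (fraction of
# matching positions over the shorter length); 0 for an empty overlap
pair_identity <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0)
  av <- strsplit(substr(a, 1L, n), "")[[1]]
  bv <- strsplit(substr(b, 1L, n), "")[[1]]
  mean(av == bv)
}

# normalized Hamming distance matrix for equal-length sequences; positions
# where either sequence has an ambiguity character (maskable, e.g. "N") are
# excluded pairwise from numerator and denominator
hamming_matrix <- function(seqs, mask_char = "N") {
  n <- length(seqs)
  if (n == 0L) return(matrix(numeric(0), 0, 0))
  lens <- unique(nchar(seqs))
  if (length(lens) != 1L)
    stop("hamming_matrix() requires equal-length sequences", call. = FALSE)
  m <- do.call(rbind, strsplit(seqs, ""))
  masked <- m == mask_char
  diff <- matrix(0, n, n)
  valid <- matrix(0, n, n)
  for (p in seq_len(ncol(m))) {
    ok <- !masked[, p]
    okp <- outer(ok, ok, "&")
    valid <- valid + okp
    diff <- diff + (okp & outer(m[, p], m[, p], "!="))
  }
  d <- ifelse(valid > 0, diff / valid, NA_real_)
  diag(d) <- 0
  dimnames(d) <- list(names(seqs), names(seqs))
  d
}

# connected components of an undirected graph given as a logical adjacency
# matrix (plain BFS; deterministic labelling by first row index)
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
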