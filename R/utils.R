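# Shared low-level helpers: sequence handling, spans, seeding, FASTA I/O.
# Spans are 0-based half-open integer vectors c(start, end) throughout.

#' Reverse complement of DNA/RNA strings
#'
#' U is treated as T; output is always DNA alphabet (ACGT).
#'
#' @param x character vector of sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    s <- chartr("ACGTUacgtu", "TGCAATGCAA", s)
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1), USE.NAMES = FALSE)
}

# uppercase, U->T, validate alphabet
norm_seq <- function(x, what = "sequence") {
  x <- chartr("u", "T", toupper(x))
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGT]", x)
  if (any(bad))
    stop(what, " contains letters outside {A,C,G,T,U}", call. = FALSE)
  x
}

# evaluate expr with a fixed RNG state, restoring the caller's state
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# span helpers ---------------------------------------------------------------

span <- function(start, end) {
  s <- as.integer(c(start, end))
  if (s[2] < s[1]) stop("span end < start", call. = FALSE)
  s
}

span_len <- function(sp) sp[2] - sp[1]

# substring by 0-based half-open span
span_seq <- function(seq, sp) substr(seq, sp[1] + 1L, sp[2])

spans_overlap <- function(a, b) a[1] < b[2] && b[1] < a[2]

# dot-bracket ---------------------------------------------------------------

#' Pairing map of a dot-bracket structure
#'
#' @param structure dot-bracket string over `(`, `)` and `.`.
#' @return integer vector; element i is the 1-based partner of position i,
#'   or `NA` if unpaired.
#' @export
pairing_map <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  n <- length(ch)
  partner <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0L)
        stop("unbalanced structure: ')' without '('", call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    } else if (ch[i] != ".") {
      stop("structure contains character other than '(', ')', '.'",
           call. = FALSE)
    }
  }
  if (length(stack) > 0L)
    stop("unbalanced structure: unmatched '('", call. = FALSE)
  partner
}

db_balanced <- function(structure) {
  ok <- TRUE
  tryCatch(pairing_map(structure), error = function(e) ok <<- FALSE)
  ok
}

# FASTA I/O (Biostrings-backed) ----------------------------------------------

#' Read a FASTA file into a named character vector
#' @param path file path.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write a named character vector of sequences to FASTA
#' @param seqs named character vector.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("sequences must be named", call. = FALSE)
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
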