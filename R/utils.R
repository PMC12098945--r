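# Shared internal helpers: amino-acid alphabet handling and small utilities.

# canonical 20-letter alphabet, alphabetical order (tie-breaks rely on this)
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# fixed background residue distribution used for sequence simulation
# (approximate database amino-acid frequencies, normalized)
AA_BACKGROUND <- c(
  A = 0.083, C = 0.014, D = 0.055, E = 0.067, F = 0.039, G = 0.071,
  H = 0.023, I = 0.059, K = 0.058, L = 0.097, M = 0.024, N = 0.041,
  P = 0.047, Q = 0.040, R = 0.055, S = 0.066, T = 0.054, V = 0.069,
  W = 0.011, Y = 0.029)
AA_BACKGROUND <- AA_BACKGROUND[AA20] / sum(AA_BACKGROUND)

# residue -> 0-based index into AA20; X (and any unknown) -> -1L
aa_index0 <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- match(chars, AA20)
  idx[is.na(idx)] <- 0L
  idx - 1L
}

split1 <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

paste0v <- function(chars) paste(chars, collapse = "")

ungap <- function(s) gsub("-", "", s, fixed = TRUE)

# validate a peptide string; returns cleaned sequence (terminal '*' stripped)
# or stops with the offending position
clean_peptide <- function(seq, id = "<seq>") {
  seq <- toupper(seq)
  seq <- sub("\\*$", "", seq)
  if (nchar(seq) == 0L)
    stop("empty sequence for record '", id, "'", call. = FALSE)
  chars <- split1(seq)
  bad <- which(!(chars %in% c(AA20, "X")))
  if (length(bad) > 0L) {
    stop("invalid character '", chars[bad[1]], "' at position ", bad[1],
         " in record '", id, "'", call. = FALSE)
  }
  seq
}

# BLOSUM62 scores for the 21-letter (AA20 + X) alphabet, cached
b62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <- e$BLOSUM62
      letters21 <- c(AA20, "X")
      cache <<- m[letters21, letters21]
    }
    cache
  }
})

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

msg_info <- function(fmt, ...) message(sprintf(fmt, ...))
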