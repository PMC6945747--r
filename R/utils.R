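# Internal sequence and interval helpers. All genomic coordinates in this
# package are 0-based half-open; R-side string indexing converts at the edge.

DNA_BASES4 <- c("A", "C", "G", "T")
BASE_COLS <- c("A", "C", "G", "T", "N")

random_dna <- function(n) {
  paste(sample(DNA_BASES4, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

chars_to_seq <- function(x) paste(x, collapse = "")

# a base drawn uniformly from the three alternatives to `cur`
other_base <- function(cur) {
  idx <- match(cur, DNA_BASES4)
  n <- length(cur)
  if (n == 0L) return(character(0))
  na <- is.na(idx)
  if (any(na)) idx[na] <- sample.int(4L, sum(na), replace = TRUE)
  shift <- sample.int(3L, n, replace = TRUE)
  DNA_BASES4[((idx - 1L + shift) %% 4L) + 1L]
}

# coerce sequences supplied as named character, DNAStringSet, or FASTA/FASTQ
# path into a named character vector
as_named_seqs <- function(x, arg = "x") {
  if (inherits(x, c("DNAStringSet", "BStringSet"))) {
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x) %||% paste0("seq", seq_along(out)))
    return(toupper(out))
  }
  if (is.character(x)) {
    if (length(x) == 1L && !grepl("^[ACGTNacgtnRYSWKM-]+$", x) && file.exists(x)) {
      fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", x)) "fastq" else "fasta"
      ss <- Biostrings::readDNAStringSet(x, format = fmt)
      return(as_named_seqs(ss))
    }
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    return(toupper(x))
  }
  stop("cannot interpret `", arg, "` as DNA sequences", call. = FALSE)
}

# interval as length-2 numeric c(start, end), 0-based half-open
as_interval <- function(x, arg = "interval") {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x) && all(c("start", "end") %in% names(x)) && nrow(x) == 1L) {
    x <- c(x$start, x$end)
  }
  if (!is.numeric(x) || length(x) != 2L || anyNA(x)) {
    stop("`", arg, "` must be a numeric c(start, end)", call. = FALSE)
  }
  if (x[1] >= x[2]) stop("`", arg, "` is empty (start >= end)", call. = FALSE)
  c(start = as.integer(x[1]), end = as.integer(x[2]))
}

as_phylo <- function(tree, arg = "tree") {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1L) {
    tr <- if (!grepl("\\(", tree) && file.exists(tree)) {
      tryCatch(ape::read.tree(tree), error = function(e) NULL)
    } else {
      tryCatch(ape::read.tree(text = tree), error = function(e) NULL,
               warning = function(w) NULL)
    }
    if (is.null(tr)) stop("failed to parse Newick in `", arg, "`", call. = FALSE)
    return(tr)
  }
  stop("`", arg, "` must be a phylo object or Newick string/file", call. = FALSE)
}

# normalize presence states to named 0/1 integer (NA = unknown)
norm_states <- function(states) {
  if (is.null(names(states))) {
    stop("`states` must be a named vector (names = tip labels)", call. = FALSE)
  }
  out <- if (is.character(states)) {
    match(tolower(states), c("absent", "present")) - 1L
  } else {
    as.integer(as.logical(states))
  }
  names(out) <- names(states)
  out
}
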