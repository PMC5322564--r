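# Independent brute-force breakpoint oracle: literally checks the
# two-consecutive-mismatch condition at every offset from each end, using
# character vectors (a different code path from the package's raw-byte
# scan).

oracle_mismatch <- function(a, b) {
  a != b | a == "N" | b == "N"
}

# smallest 0-based offset k such that positions k and k+1 both mismatch,
# testing every offset explicitly
oracle_forward <- function(obs, ref) {
  o <- strsplit(obs, "", fixed = TRUE)[[1]]
  r <- strsplit(ref, "", fixed = TRUE)[[1]]
  m <- min(length(o), length(r))
  hits <- integer(0)
  for (k in seq_len(m - 1L)) {
    if (oracle_mismatch(o[k], r[k]) && oracle_mismatch(o[k + 1L], r[k + 1L])) {
      hits <- c(hits, k - 1L)
    }
  }
  if (length(hits)) min(hits) else NA_integer_
}

# mirror from the right; returned offset is the reference coordinate just
# after the last disrupted reference base (half-open end)
oracle_reverse <- function(obs, ref) {
  o <- rev(strsplit(obs, "", fixed = TRUE)[[1]])
  r <- rev(strsplit(ref, "", fixed = TRUE)[[1]])
  m <- min(length(o), length(r))
  hits <- integer(0)
  for (k in seq_len(m - 1L)) {
    if (oracle_mismatch(o[k], r[k]) && oracle_mismatch(o[k + 1L], r[k + 1L])) {
      hits <- c(hits, k - 1L)
    }
  }
  if (length(hits)) nchar(ref) - min(hits) else NA_integer_
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random (ref, obs) pair: substitutions and optionally one indel
random_obs_pair <- function(min_len = 20L, max_len = 60L) {
  len <- sample(min_len:max_len, 1L)
  ref <- random_dna(len)
  obs <- ref
  n_sub <- sample(0:3, 1L)
  if (n_sub > 0L) {
    chars <- strsplit(obs, "", fixed = TRUE)[[1]]
    for (p in sample(len, n_sub)) {
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
    }
    obs <- paste(chars, collapse = "")
  }
  kind <- sample(c("none", "del", "ins"), 1L)
  if (kind == "del") {
    L <- sample(1:6, 1L)
    s <- sample(0:(len - L), 1L)
    obs <- paste0(substr(obs, 1L, s), substr(obs, s + L + 1L, nchar(obs)))
  } else if (kind == "ins") {
    L <- sample(1:6, 1L)
    s <- sample(0:nchar(obs), 1L)
    obs <- paste0(substr(obs, 1L, s), random_dna(L),
                  substr(obs, s + 1L, nchar(obs)))
  }
  list(ref = ref, obs = obs)
}

# exact read pair (no errors) for a molecule, with flat qualities
exact_pair <- function(molecule, read_length = 150L, q = 37L) {
  len <- nchar(molecule)
  fl <- min(read_length, len)
  fwd <- substr(molecule, 1L, fl)
  rev_tpl <- substr(molecule, max(1L, len - read_length + 1L), len)
  rev <- reverse_complement(rev_tpl)
  data.frame(read_id = "m1",
             forward_seq = fwd, reverse_seq = rev,
             forward_qual = strrep(intToUtf8(q + 33L), nchar(fwd)),
             reverse_qual = strrep(intToUtf8(q + 33L), nchar(rev)),
             stringsAsFactors = FALSE)
}

# minimal hand-built call row for spectrum tests
make_call <- function(status = "wildtype_like", ds = NA_integer_,
                      de = NA_integer_, ins = "", f = NA_integer_,
                      r = NA_integer_, ldiff = NULL, sample_id = NULL) {
  if (is.null(ldiff)) {
    dl <- if (is.na(ds)) 0L else de - ds
    ldiff <- nchar(ins) - dl
  }
  row <- data.frame(read_id = "x", forward_breakpoint = f,
                    reverse_breakpoint = r, deletion_start = ds,
                    deletion_end = de, inserted_sequence = ins,
                    status = status, length_difference = ldiff,
                    note = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(sample_id)) row$sample_id <- sample_id
  row
}
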