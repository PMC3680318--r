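# shared fixture builders (everything is generated in code at test time)

rdna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# a sequence with one planted inverted repeat: arm + interior + revcomp(arm)
planted_ir <- function(arm_len, interior_len, pad = 50L) {
  arm <- rdna(arm_len)
  while (is_simple_arm(arm)) arm <- rdna(arm_len)
  list(seq = paste0(rdna(pad), arm, rdna(interior_len),
                    reverse_complement(arm), rdna(pad)),
       arm = arm, left_start = pad,
       right_end = pad + 2L * arm_len + interior_len)
}

write_temp_fasta <- function(seqs, envir = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".fasta", .local_envir = envir)
  write_fasta(seqs, path)
  path
}

# identity of two equal-anchored strings over the shorter length
str_identity <- function(a, b) {
  m <- min(nchar(a), nchar(b))
  sum(strsplit(substr(a, 1, m), "")[[1]] ==
        strsplit(substr(b, 1, m), "")[[1]]) / m
}
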