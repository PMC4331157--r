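# Small in-code fixtures shared across test files.

# CT table builder: `wells` is a named list assay -> numeric vector (one
# value per sample); the control assay defaults to a flat 20 cycles.
make_ct <- function(wells, groups, control = NULL) {
  n <- length(groups)
  if (is.null(control)) control <- rep(20, n)
  m <- cbind(U6 = control, do.call(cbind, wells))
  rownames(m) <- sprintf("s%02d", seq_len(n))
  ct_table(m, group_labels = groups, control_assay_id = "U6")
}

# numeric vector of length 2 with exact mean m and sd s
two_point <- function(m, s) m + c(-1, 1) * s / sqrt(2)

# default two-group labels: nc case then nr reference
labels_mpm <- function(nc, nr) c(rep("MPM", nc), rep("BAPE", nr))
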