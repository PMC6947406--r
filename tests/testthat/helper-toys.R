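# small hand-built datasets shared across test files

# 2 subjects x 2 times, q = 1, p = 2
toy_data <- function() {
  longitudinal_data(
    y = c(1, 2, 3, 4),
    X = matrix(c(0.5, -1, 2, 0.25,
                 1.5, 0.75, -0.5, 1), 4, 2),
    E = matrix(c(1, 1, 0, 0), 4, 1),
    id = c("a", "a", "b", "b"))
}

# single-row dataset for Kronecker-order checks: X = (2, 3), E = (1, 0, 0)
kron_row_data <- function() {
  longitudinal_data(y = 0, X = matrix(c(2, 3), 1, 2),
                    E = matrix(c(1, 0, 0), 1, 3), id = 1)
}

# permute subjects of a longitudinal_data consistently
permute_subjects <- function(data, perm) {
  subset_subjects(data, data$subject_ids[perm])
}
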