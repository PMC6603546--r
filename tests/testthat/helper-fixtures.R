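# shared toy dialects, builders and geometry helpers

toy_chain <- function() {
  skeleton_dialect("toy3", c("A", "B", "C"),
                   rbind(c("A", "B"), c("B", "C")))
}

toy_pair <- function() {
  skeleton_dialect("toyV", c("Root", "TipLeft", "TipRight"),
                   rbind(c("Root", "TipLeft"), c("Root", "TipRight")),
                   list(c("Root-TipLeft", "Root-TipRight")))
}

# sequence from a list of n_joints x 3 matrices at 30 Hz
make_seq <- function(dialect, poses, state = "tracked") {
  nf <- length(poses)
  pos <- array(NA_real_, dim = c(nf, dialect$n_joints, 3L))
  for (i in seq_len(nf)) pos[i, , ] <- poses[[i]]
  skeleton_sequence((seq_len(nf) - 1) / 30, pos, state, dialect)
}

# a reference table with known per-class lengths, bypassing estimation
build_ref_table <- function(dialect, class_lengths) {
  stopifnot(length(class_lengths) == length(dialect$class_names))
  tab <- data.frame(class = dialect$class_names,
                    l_ref_initial = class_lengths,
                    l_ref_final = class_lengths,
                    n_observations = 0L,
                    weight_sum_initial = 1,
                    weight_sum_final = 1,
                    stringsAsFactors = FALSE)
  attr(tab, "dialect") <- dialect$name
  class(tab) <- c("bone_reference_table", "data.frame")
  tab
}

# random proper rotation matrix
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# per-class ground-truth lengths for a generator run
true_class_lengths <- function(sim) {
  d <- sim$truth$dialect
  vapply(split(sim$true_lengths, d$bone_class), mean, numeric(1))
}
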