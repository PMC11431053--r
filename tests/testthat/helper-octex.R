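# Shared fixtures and independent oracles, built in code at test time.

# Brute-force double-loop implementation of the residual encoding
# (independent oracle for assign_weights / texture_encode).
encode_oracle <- function(X, C, s) {
  N <- nrow(X); K <- nrow(C); D <- ncol(X)
  logits <- matrix(0, N, K)
  for (i in seq_len(N)) {
    for (k in seq_len(K)) {
      r <- X[i, ] - C[k, ]
      logits[i, k] <- -s[k] * sum(r * r)
    }
  }
  a <- matrix(0, N, K)
  for (i in seq_len(N)) {
    e <- exp(logits[i, ] - max(logits[i, ]))
    a[i, ] <- e / sum(e)
  }
  E <- matrix(0, K, D)
  for (k in seq_len(K)) {
    for (i in seq_len(N)) {
      E[k, ] <- E[k, ] + a[i, k] * (X[i, ] - C[k, ])
    }
  }
  list(a = a, E = E)
}

# Cohort with a fixed number of patients per class (one class per patient).
make_balanced_cohort <- function(n_per_class, volumes_per_patient = 2L,
                                 config = synthetic_config(), seed = 1L) {
  classes <- oct_classes()
  merged <- NULL
  for (ci in seq_along(classes)) {
    mix <- as.numeric(classes == classes[ci])
    names(mix) <- classes
    co <- generate_cohort(n_per_class, mix, volumes_per_patient, config,
                          seed = seed * 100L + ci)
    for (j in seq_along(co$patients)) {
      pid <- sprintf("P%s%03d", classes[ci], j)
      co$patients[[j]]$patient_id <- pid
      for (v in seq_along(co$patients[[j]]$volumes)) {
        co$patients[[j]]$volumes[[v]]$volume$patient_id <- pid
      }
    }
    if (is.null(merged)) merged <- co
    else merged$patients <- c(merged$patients, co$patients)
  }
  merged
}

# Ground-truth oracle risk grid: a patch is certain high-risk iff the
# lesion mask covers at least `overlap` of its window.
oracle_risk <- function(sv, window_size, stride, overlap = 0.5) {
  nf <- length(sv$volume$frames)
  W <- ncol(sv$volume$frames[[1]])
  offsets <- seq.int(0L, W - window_size, by = stride)
  risk <- matrix(0, nf, length(offsets))
  for (f in seq_len(nf)) {
    for (w in seq_along(offsets)) {
      xs <- offsets[w] + seq_len(window_size)
      risk[f, w] <- as.numeric(mean(sv$lesion_mask[f, xs]) >= overlap)
    }
  }
  risk
}

# Deterministic class-balanced subsample of a patch dataset.
subsample_patches <- function(ds, n_per_class, seed = 1L) {
  idx <- octex:::with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(ds$meta)), ds$meta$class), function(ii) {
      if (length(ii) > n_per_class) sort(sample(ii, n_per_class)) else ii
    }), use.names = FALSE)
  })
  ds$patches <- ds$patches[idx]
  ds$meta <- ds$meta[idx, , drop = FALSE]
  ds
}

subset_patches_by_patient <- function(ds, ids, keep = TRUE) {
  sel <- ds$meta$patient_id %in% ids
  if (!keep) sel <- !sel
  ds$patches <- ds$patches[sel]
  ds$meta <- ds$meta[sel, , drop = FALSE]
  ds
}
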