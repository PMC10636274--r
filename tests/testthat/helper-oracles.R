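# Independent oracles and fixture builders shared across the test files.

# All non-negative integer k-vectors summing to n.
compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, 1L, 1L))
  do.call(rbind, lapply(0:n, function(i) cbind(i, compositions(n - i, k - 1L))))
}

# Brute-force natural isotopic distribution: enumerate the multinomial
# isotope compositions of every element and combine them exhaustively (no
# convolution anywhere, unlike the implementation).
oracle_natural_distribution <- function(formula,
                                        isotopes = default_isotope_table()) {
  formula <- formula[formula > 0]
  tabs <- lapply(names(formula), function(el) {
    d <- isotopes[[el]]
    shifts <- d$mass_number - d$mass_number[1L]
    comps <- compositions(formula[[el]], nrow(d))
    data.frame(shift = as.vector(comps %*% shifts),
               prob = apply(comps, 1L, function(kv)
                 stats::dmultinom(kv, prob = d$abundance)))
  })
  joint <- Reduce(function(a, b) {
    g <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
    data.frame(shift = a$shift[g$i] + b$shift[g$j],
               prob = a$prob[g$i] * b$prob[g$j])
  }, tabs)
  out <- numeric(max(joint$shift) + 1L)
  for (r in seq_len(nrow(joint)))
    out[joint$shift[r] + 1L] <- out[joint$shift[r] + 1L] + joint$prob[r]
  out
}

# Brute-force dual-tracer high-res matrix entry for formula {C:2, N:1},
# tracers 13C (n=2) and 15N (n=1): enumerate each unlabeled atom's
# heavy/light state individually and keep only species landing exactly on
# the tracer channel grid (everything else is mass-resolved away).
oracle_dual_highres_c2n1 <- function(isotopes = default_isotope_table()) {
  pC <- isotopes$C$abundance[2L]
  pN <- isotopes$N$abundance[2L]
  states <- expand.grid(n = 0:1, c = 0:2)[, c("c", "n")]   # row-major, C outer
  M <- matrix(0, 6L, 6L)
  for (s in seq_len(nrow(states))) {
    j1 <- states$c[s]; j2 <- states$n[s]
    natC <- 2L - j1; natN <- 1L - j2
    atoms <- expand.grid(rep(list(0:1), natC + natN))
    if (natC + natN == 0L) atoms <- data.frame(row.names = 1L)
    for (a in seq_len(max(nrow(atoms), 1L))) {
      heavy <- if (ncol(atoms)) as.integer(atoms[a, ]) else integer(0)
      hC <- if (natC) sum(heavy[seq_len(natC)]) else 0L
      hN <- if (natN) sum(heavy[natC + seq_len(natN)]) else 0L
      prob <- prod(c(ifelse(heavy[seq_len(natC)] == 1L, pC, 1 - pC),
                     ifelse(heavy[natC + seq_len(natN)] == 1L, pN, 1 - pN)),
                   na.rm = TRUE)
      i1 <- j1 + hC; i2 <- j2 + hN
      row <- which(states$c == i1 & states$n == i2)
      if (length(row)) M[row, s] <- M[row, s] + prob
    }
  }
  M
}

# Deterministic single-peak synthetic run for chromatography tests.
make_gaussian_run <- function(apex_rt = 300, sigma = 4, apex = 1e6,
                              mzs = 152.0, fractions = 1, rt_step = 0.5,
                              rt_range = c(240, 360), baseline = 0,
                              drift = 0) {
  rt <- seq(rt_range[1], rt_range[2], by = rt_step)
  shape <- exp(-(rt - apex_rt)^2 / (2 * sigma^2))
  scans <- lapply(seq_along(rt), function(i) {
    inten <- apex * fractions * shape[i] + baseline + drift * (rt[i] - rt[1])
    ms_scan(rt[i], mz = mzs, intensity = inten, polarity = "positive")
  })
  ms_run(scans)
}

# Minimal single-tracer glutamine method (6 carbon channels).
gln_c13_method <- function(expected_rt = 300, rt_window = 30, ...) {
  t <- target_ion("glutamine", ion = "[M+H]+", formula = "C5H11N2O3",
                  charge = 1, base_mz = 147.07642,
                  tracers = tracer_spec("C", 13, 5),
                  expected_rt = expected_rt, rt_window = rt_window)
  ms_method(list(t), ...)
}

# Minimal hand-written mzXML (3.2) with one scan; RT given as an ISO-8601
# duration attribute, peaks as network-order 32-bit floats.
write_tiny_mzxml <- function(path, rt_attr = "PT1.5S",
                             mz = c(100, 200), inten = c(55.5, 99)) {
  pk <- as.numeric(rbind(mz, inten))
  b64 <- gsub("[\r\n]", "",
              jsonlite::base64_enc(writeBin(pk, raw(), size = 4L, endian = "big")))
  xml <- paste0(
    '<?xml version="1.0" encoding="ISO-8859-1"?>\n',
    '<mzXML xmlns="http://sashimi.sourceforge.net/schema_revision/mzXML_3.2">\n',
    '<msRun scanCount="1">\n',
    '<scan num="1" msLevel="1" peaksCount="', length(mz),
    '" retentionTime="', rt_attr, '" polarity="+">\n',
    '<peaks compressionType="none" compressedLen="', length(pk) * 4L,
    '" precision="32" byteOrder="network" contentType="m/z-int">',
    b64, '</peaks>\n</scan>\n</msRun>\n</mzXML>\n')
  writeLines(xml, path)
  path
}

# mzML skeleton with an empty spectrum list (degenerate "no scans" input).
write_empty_mzml <- function(path) {
  run <- ms_run(list(ms_scan(1, 100, 1)))
  tmp <- tempfile(fileext = ".mzML")
  write_run(run, tmp, compression = "none")
  txt <- paste(readLines(tmp), collapse = "\n")
  txt <- sub('<spectrumList count="1"[^>]*>.*</spectrumList>',
             '<spectrumList count="0" defaultDataProcessingRef="DP1"></spectrumList>',
             txt)
  writeLines(txt, path)
  path
}
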