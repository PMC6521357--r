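# Shared fixtures: tiny methylomes and a small cached synthetic model.

toyMethylome <- function(pos = c(100L, 210L, 320L, 430L, 540L),
                         mc = c(5L, 8L, 2L, 9L, 1L),
                         t = rep(10L, length(pos)),
                         chrom = "chr1", sampleId = "toy",
                         context = "CG", strand = "+") {
  Methylome(data.frame(chrom = chrom, pos = pos, strand = strand,
                       context = context, mc = mc, t = t),
            sampleId = sampleId, context = context)
}

writeMethylomeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  path
}

# small model shared by dmr/cli tests; cached in the helper environment
.modelCache <- new.env(parent = emptyenv())
smallModel <- function() {
  if (is.null(.modelCache$model))
    .modelCache$model <- suppressWarnings(trainSyntheticModel(
      seed = 7L,
      cfg = SimConfig(nDmr = 40L, nNonDmr = 100L, coverageMean = 25)))
  .modelCache$model
}

# independent optimiser for the same ridge-penalised weighted deviance
refWlogitLRT <- function(levels, labels, weights, ridge = 1e-4) {
  devAt <- function(b) {
    mu <- pmin(pmax(plogis(b[1] + b[2] * levels), 1e-12), 1 - 1e-12)
    -2 * sum(weights * (labels * log(mu) + (1 - labels) * log(1 - mu)))
  }
  grAt <- function(b) {
    mu <- plogis(b[1] + b[2] * levels)
    c(-2 * sum(weights * (labels - mu)),
      -2 * sum(weights * (labels - mu) * levels) + 2 * ridge * b[2])
  }
  mu0 <- sum(weights * labels) / sum(weights)
  devNull <- -2 * sum(weights * (labels * log(mu0) +
                                   (1 - labels) * log(1 - mu0)))
  fit <- nlminb(c(log(mu0 / (1 - mu0)), 0),
                function(b) devAt(b) + ridge * b[2]^2, gradient = grAt,
                control = list(iter.max = 5000, rel.tol = 1e-15,
                               abs.tol = 1e-20))
  stat <- max(devNull - (fit$objective - ridge * fit$par[2]^2), 0)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

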