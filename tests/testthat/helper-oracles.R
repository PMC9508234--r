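# Independent brute-force oracles and shared small fixtures.

# Sen slope by direct double-loop enumeration of pairwise slopes
oracleSenSlope <- function(x, t = seq_along(x)) {
  sl <- c()
  n <- length(x)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (!is.na(x[i]) && !is.na(x[j]))
      sl <- c(sl, (x[j] - x[i]) / (t[j] - t[i]))
  median(sl)
}

# Mann-Kendall S by direct double loop
oracleMkS <- function(x) {
  s <- 0
  n <- length(x)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    s <- s + sign(x[j] - x[i])
  s
}

# R/S statistic by direct transcription of the block definition
oracleRs <- function(x, m) {
  nb <- length(x) %/% m
  vals <- c()
  for (b in seq_len(nb)) {
    seg <- x[((b - 1) * m + 1):(b * m)]
    mu <- mean(seg)
    X <- cumsum(seg - mu)
    R <- max(X) - min(X)
    S <- sqrt(sum((seg - mu)^2) / m)
    if (S > 0) vals <- c(vals, R / S)
  }
  mean(vals)
}

# small scenes are expensive enough to share across tests
.sceneCache <- new.env(parent = emptyenv())
cachedScene <- function(key, config) {
  if (is.null(.sceneCache[[key]]))
    .sceneCache[[key]] <- generateScene(config)
  .sceneCache[[key]]
}

smallScene <- function(noise = 0.02, seed = 11)
  cachedScene(paste0("s", noise, "_", seed),
              sceneConfig(nRows = 40, nCols = 48, ndviNoiseSd = noise,
                          seed = seed))

# single-region climate-only scene for regression tests
regressionScene <- function(noise, seed = 21, nr = 40, nc = 40)
  cachedScene(paste0("r", noise, "_", seed, "_", nr),
              sceneConfig(nRows = nr, nCols = nc,
                          regions = list(list(
                            name = "resp",
                            coef = c(temperature = 0.10,
                                     precipitation = 0.001,
                                     sunshine = -0.0001),
                            baseNdvi = 0.5, humanTrend = 0)),
                          ndviNoiseSd = noise, seed = seed))

# the verbatim 36-row scenario lookup (independent of scenarioTable())
verbatimScenarioRows <- function() {
  txt <- c(
    "1 CDI CDNI CDCD",  "1 CDI CDNI BDCD",  "1 CDI BDNI CDCD",
    "2 HDI HDNI HDCD",  "2 HDI HDNI BDCD",  "2 HDI BDNI HDCD",
    "3 BDI CDNI HDCD",  "3 BDI HDNI CDCD",  "3 BDI BDNI BDCD",
    "4 CDSR CDNI CDCI", "4 CDSR CDNI BDCI", "4 CDSR BDNI CDCI",
    "5 HDSR HDNI HDCI", "5 HDSR HDNI BDCI", "5 HDSR BDNI HDCI",
    "6 BDSR CDNI HDCI", "6 BDSR HDNI CDCI", "6 BDSR BDNI BDCI",
    "7 CDMD CDND CDCI", "7 CDMD CDND BDCI", "7 CDMD BDND CDCI",
    "8 HDMD HDND HDCI", "8 HDMD HDND BDCI", "8 HDMD BDND HDCI",
    "9 BDMD CDND HDCI", "9 BDMD HDND CDCI", "9 BDMD BDND BDCI",
    "10 CDSD CDND CDCD", "10 CDSD CDND BDCD", "10 CDSD BDND CDCD",
    "11 HDSD HDND HDCD", "11 HDSD HDND BDCD", "11 HDSD BDND HDCD",
    "12 BDSD CDND HDCD", "12 BDSD HDND CDCD", "12 BDSD BDND BDCD")
  out <- do.call(rbind, strsplit(txt, " "))
  data.frame(scenario = as.integer(out[, 1]), label = out[, 2],
             ndviDriver = out[, 3], cvDriver = out[, 4],
             stringsAsFactors = FALSE)
}
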