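make_epochs <- function(data, fs = 1000, window = c(-200, 500)) {
  eeg_epochs(data, fs, window, paste0("ch", seq_len(dim(data)[2])))
}

test_that("band-pass keeps the passband and rejects stopband and DC", {
  fs <- 1000
  t <- seq_len(2000) / fs
  in_band <- sin(2 * pi * 10 * t)
  out_band <- sin(2 * pi * 40 * t)
  x <- rbind(in_band, out_band, 1 + 0 * t)
  y <- bandpass(x, 1, 20, fs = fs)
  mid <- 500:1500
  gain_in <- sqrt(mean(y[1, mid]^2)) / sqrt(mean(in_band[mid]^2))
  gain_out <- sqrt(mean(y[2, mid]^2)) / sqrt(mean(out_band[mid]^2))
  expect_lt(abs(gain_in - 1), 0.05)
  expect_lt(20 * log10(gain_out), -20)
  expect_lt(abs(mean(y[3, mid])), 1e-3)
  expect_error(bandpass(x, 10, 600, fs = fs),
               class = "erpgraph_invalid_argument")
})

test_that("zero-phase filtering reproduces frozen reference output", {
  # expected values computed once with an independent reference
  # implementation of the odd-reflection filtfilt schedule on this exact
  # deterministic input and filter
  bt <- signal::butter(2, c(0.1, 0.3), "pass")
  tt <- 0:99
  x <- sin(0.1 * tt) + 0.5 * cos(0.731 * tt)
  expected <- c(
    0.014242364500, -0.152914349067, -0.332754823689, -0.487280163159,
    -0.534512309727, -0.407774703954, -0.118570749666, 0.227716895975,
    0.478122388030, 0.513572176198, 0.316945169246, -0.012539964211,
    -0.307875178669, -0.420014080630, -0.295101351312, -0.002345026039,
    0.302024942800, 0.455834872014, 0.374993444621, 0.097104667052,
    -0.237682397838, -0.458616121028, -0.452066051343, -0.220023211418,
    0.120585752125, 0.397411988094, 0.470581116038, 0.304036196382,
    -0.016131057102, -0.325719725699, -0.466320820475, -0.366212669455,
    -0.076928729537, 0.253169163041, 0.454791765266, 0.424302207444,
    0.176728467302, -0.161880624803, -0.418847845644, -0.463101732691,
    -0.272162519366, 0.056352647551, 0.354587859407, 0.470196628236,
    0.344167010200, 0.040958426061, -0.284447901760, -0.465747620047,
    -0.410291885466, -0.146423951265, 0.191013354344, 0.429592254656,
    0.447420684083, 0.235438843646, -0.097942706215, -0.382234991884,
    -0.471989432805, -0.321127922793, -0.006502822714, 0.311352539067,
    0.470228469103, 0.389097939788, 0.109493577903, -0.225736606551,
    -0.445435185248, -0.437593942640, -0.206571244992, 0.129172399044,
    0.397665442305, 0.461380972133, 0.287607104134, -0.034738251022,
    -0.340458233272, -0.472439889952, -0.361936793472, -0.063754233483,
    0.271646749912, 0.474879955118, 0.443988952110, 0.196279186008,
    -0.140888703944, -0.395643447738, -0.439918052435, -0.255222895588,
    0.057986104705, 0.332319909421, 0.420208689434, 0.270639487670,
    -0.043994384912, -0.365118359327, -0.529952195621, -0.454995123308,
    -0.176483674494, 0.173749103008, 0.442741060134, 0.537659772608,
    0.465391574578, 0.307114370857, 0.147680139062, 0.014546448002
  )
  got <- erpgraph:::filtfilt_mat(bt$b, bt$a, x)
  expect_equal(got, expected, tolerance = 1e-9)
  # matrix input filters each column identically
  two <- erpgraph:::filtfilt_mat(bt$b, bt$a, cbind(x, 2 * x))
  expect_equal(two[, 1], expected, tolerance = 1e-9)
  expect_equal(two[, 2], 2 * expected, tolerance = 1e-9)
})

test_that("epoching yields 700 samples at 1 kHz and counts drops", {
  cont <- matrix(rnorm(2 * 30000), 2, 30000)
  onsets <- seq(1000, 29000, length.out = 25)  # 5 vocalizations x 5 perturbations
  ep <- epoch_data(cont, 1000, onsets, c(-200, 500))
  expect_equal(dim(ep$data), c(25, 2, 700))
  expect_equal(attr(ep, "n_dropped"), 0)
  # an onset at sample 1 cannot host the pre-stimulus window
  expect_warning(ep0 <- epoch_data(cont, 1000, 1, c(-200, 500)),
                 "out-of-bounds")
  expect_equal(dim(ep0$data)[1], 0)
  # trial content is the raw window
  expect_equal(ep$data[1, , ], cont[, (1000 - 200):(1000 + 499)])
})

test_that("artifact rejection drops exactly the over-threshold trials", {
  co <- small_cohort(n_trials = 60)
  ep <- co$subjects[[1]]
  clean <- reject_artifacts(ep, p2p_threshold = 1e6)
  expect_true(all(clean$keep))
  p2p <- apply(ep$data, 1, function(tr) max(apply(tr, 1, function(ch)
    diff(range(ch)))))
  inj <- inject_artifacts(ep, 0.25, amplitude = 4 * max(p2p), seed = 2)
  out <- reject_artifacts(inj$epochs, p2p_threshold = max(p2p) * 1.01)
  sens <- sum(!out$keep & inj$mask) / sum(inj$mask)
  expect_gte(sens, 0.95)
  expect_equal(sum(out$keep) + sum(!out$keep), dim(ep$data)[1])
  expect_error(reject_artifacts(ep, p2p_threshold = 1e-9),
               class = "erpgraph_invalid_state")
})

test_that("mastoid re-referencing removes the common mode", {
  m <- generate_montage(6)
  dat <- array(rnorm(4 * 6 * 700), dim = c(4, 6, 700))
  ep <- eeg_epochs(dat, 1000, c(-200, 500), m$label)
  midx <- match(erpgraph:::mastoid_labels(m), m$label)
  # zero mastoids: identity
  ep0 <- ep
  ep0$data[, midx, ] <- 0
  expect_equal(rereference_mastoid(ep0, m)$data, ep0$data)
  # constant topography: all-zero output
  epc <- ep
  epc$data[] <- 3.14
  expect_equal(max(abs(rereference_mastoid(epc, m)$data)), 0)
  # general input: mastoid mean of the output is 0 at every sample
  out <- rereference_mastoid(ep, m)
  mm <- (out$data[, midx[1], ] + out$data[, midx[2], ]) / 2
  expect_lt(max(abs(mm)), 1e-12)
  bad <- m
  bad$label[midx[1]] <- "nonsense"
  expect_error(rereference_mastoid(ep, bad),
               class = "erpgraph_invalid_argument")
})

test_that("baseline correction zeroes the pre-stimulus mean and is idempotent", {
  co <- small_cohort(n_trials = 5)
  ep <- co$subjects[[1]]
  out <- baseline_correct(ep)
  tm <- epoch_times(out)
  bl <- apply(out$data[, , tm >= -200 & tm < 0], c(1, 2), mean)
  expect_lt(max(abs(bl)), 1e-10)
  expect_equal(baseline_correct(out)$data, out$data, tolerance = 1e-12)
  const <- ep
  const$data[] <- 2
  expect_equal(max(abs(baseline_correct(const)$data)), 0)
  expect_error(baseline_correct(ep, c(-500, -300)),
               class = "erpgraph_invalid_argument")
})

test_that("trial averaging is the arithmetic mean", {
  dat <- array(0, dim = c(4, 3, 700))
  dat[1, 1, 10] <- 1; dat[2, 1, 10] <- 1; dat[3, 1, 10] <- 1; dat[4, 1, 10] <- 1
  ep <- make_epochs(dat)
  expect_equal(average_erp(ep)$data[1, 10], 1)
  x <- array(rnorm(2 * 3 * 700), dim = c(2, 3, 700))
  x[2, , ] <- -x[1, , ]
  expect_equal(max(abs(average_erp(make_epochs(x))$data)), 0)
  ident <- array(rep(rnorm(3 * 700), each = 5), dim = c(5, 3, 700))
  expect_equal(average_erp(make_epochs(ident))$data,
               matrix(ident[1, , ], 3, 700), tolerance = 1e-12)
})

test_that("re-reference and baseline commute on zero-mastoid data", {
  m <- generate_montage(8)
  dat <- array(rnorm(3 * 8 * 700), dim = c(3, 8, 700))
  midx <- match(erpgraph:::mastoid_labels(m), m$label)
  dat[, midx, ] <- 0
  ep <- eeg_epochs(dat, 1000, c(-200, 500), m$label)
  a <- baseline_correct(rereference_mastoid(ep, m))
  b <- rereference_mastoid(baseline_correct(ep), m)
  expect_equal(a$data, b$data, tolerance = 1e-12)
})
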