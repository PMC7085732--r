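# Network construction, shape arithmetic, training contract, prediction.

test_that("feature-map widths follow the floor(w/5) pooling recursion", {
  for (w in c(125L, 126L, 300L, 624L, 625L, 1001L, 3003L)) {
    model <- build_network(w)
    oracle <- w
    expected <- integer(4)
    for (b in 1:4) {
      if (b <= 3) oracle <- oracle %/% 5L
      expected[b] <- oracle
    }
    expect_equal(network_forward_widths(model), expected, label = paste("w =", w))
  }
  # the canonical 1001-wide case spelled out
  expect_equal(network_forward_widths(build_network(1001L)),
               c(200L, 40L, 8L, 8L))
})

test_that("layer parameter counts match closed-form arithmetic", {
  model <- build_network(1001L)
  conv1 <- model$layers[[1]]
  expect_equal(length(conv1$W) + length(conv1$b), 5 * 1 * 16 + 16)  # 96
  fc <- model$layers[[5]]
  expect_equal(dim(fc$W), c(8 * 128, 2))
})

test_that("configuration invariants are enforced", {
  expect_fallcnn_error(network_config(filters = c(32, 16, 64, 128)),
                       "fallcnn_config_error", "increasing")
  expect_silent(network_config(filters = c(16, 32, 64, 128)))
  expect_fallcnn_error(build_network(124L), "fallcnn_config_error", "125")
  expect_fallcnn_error(train_config(learning_rate = 0), "fallcnn_config_error")
  expect_fallcnn_error(train_config(validation_patience = 0),
                       "fallcnn_config_error")
})

test_that("softmax probabilities are normalized for arbitrary inputs", {
  model <- build_network(125L, seed = 3)
  x <- fallcnn:::with_seed(3, matrix(stats::rnorm(20 * 125, 0, 20), 20, 125))
  pred <- predict(model, x)
  expect_lt(max(abs(rowSums(pred$probs) - 1)), 1e-6)
  expect_true(all(pred$probs >= 0))
})

test_that("prediction resolves exact probability ties to FALL", {
  model <- build_network(125L, seed = 1)
  nb <- model$config$n_blocks
  model$layers[[nb + 1]]$W[] <- 0     # logits = bias only
  model$layers[[nb + 1]]$b <- c(0, 0) # exact 0.5 / 0.5
  x <- matrix(1, 4, 125)
  pred <- predict(model, x)
  expect_true(all(pred$probs == 0.5))
  expect_equal(as.character(pred$labels), rep("FALL", 4))
  model$layers[[nb + 1]]$b <- c(10, -10)  # decisive ADL logits
  expect_equal(as.character(predict(model, x)$labels), rep("ADL", 4))
})

test_that("prediction rejects width mismatches, naming both widths", {
  model <- build_network(125L)
  expect_fallcnn_error(predict(model, matrix(0, 2, 130)),
                       "fallcnn_width_error", "125.*130")
})

test_that("training is deterministic under a fixed seed", {
  wins <- toy_windows(24)
  run <- function() {
    m <- build_network(125L, seed = 5)
    train_network(m, wins$x, wins$labels, wins$x[1:8, ], wins$labels[1:8],
                  train_config(max_epochs = 4, minibatch_size = 8, seed = 5))
  }
  m1 <- run(); m2 <- run()
  expect_identical(m1$history, m2$history)
  expect_identical(m1$layers, m2$layers)
})

test_that("training rejects single-class training sets", {
  wins <- toy_windows(12)
  adl <- wins$labels == "ADL"
  expect_fallcnn_error(
    train_network(build_network(125L), wins$x[adl, ], wins$labels[adl],
                  wins$x, wins$labels, quick_tc()),
    "fallcnn_config_error", "single class")
})

test_that("early stopping fires after patience consecutive non-improvements", {
  wins <- toy_windows(24)
  flipped <- factor(ifelse(wins$labels == "ADL", "FALL", "ADL"),
                    levels = c("ADL", "FALL"))
  m <- build_network(125L, seed = 5)
  # validating against flipped labels makes validation loss rise as the
  # network fits: a forced-degradation fixture
  m <- train_network(m, wins$x, wins$labels, wins$x, flipped,
                     train_config(learning_rate = 0.01, minibatch_size = 8,
                                  seed = 5))
  expect_true(m$early_stopped)
  expect_equal(nrow(m$history), m$best_epoch + 3L)  # 1 + patience evaluations
  expect_lt(nrow(m$history), 20L)
  expect_true(all(diff(m$history$val_loss) > 0))
})

test_that("the epoch count never exceeds the configured maximum", {
  wins <- toy_windows(16)
  m <- train_network(build_network(125L, seed = 2), wins$x, wins$labels,
                     wins$x, wins$labels, train_config(seed = 2))
  expect_lte(nrow(m$history), 20L)
  expect_lte(m$best_epoch, nrow(m$history))
})

test_that("the architecture can memorize a 64-window set (capacity check)", {
  dat <- fallcnn:::with_seed(10, {
    x <- matrix(stats::rnorm(64 * 125, 9.8, 1), 64, 125)
    y <- factor(sample(c("ADL", "FALL"), 64, TRUE), levels = c("ADL", "FALL"))
    list(x = x, y = y)
  })
  m <- build_network(125L, seed = 6)
  m <- train_network(m, dat$x, dat$y, dat$x, dat$y,
                     train_config(learning_rate = 0.01, minibatch_size = 8,
                                  dropout_rate = 0, validation_patience = 20,
                                  seed = 6))
  expect_lt(tail(m$history$train_loss, 1), 0.05)
  expect_equal(tail(m$history$train_acc, 1), 1)
})
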