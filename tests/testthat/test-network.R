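# Reduced-width models keep these tests fast; widths scale uniformly so
# the wiring is identical to the full-size networks.

test_that("build_model is deterministic and validates its grid", {
  cfg <- tiny_cpt_config()
  m1 <- build_model(cfg, seed = 5)
  m2 <- build_model(cfg, seed = 5)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(cfg, seed = 6)
  expect_false(identical(m1$params, m3$params))
  expect_error(cpt_config("cpt", branches = 1), "2 branches")
  expect_error(cpt_config("parallel_vit", branches = 1), "branches >= 2")
  expect_error(cpt_config("cpt", image_size = 100), "divisible")
  expect_error(cpt_config("cpt", dd_layers = 3), "0, 1 or 2")
})

test_that("hybrid encoder produces the expected token grid and skips", {
  cfg <- tiny_cpt_config()
  m <- build_model(cfg, seed = 1)
  img <- array(runif(64 * 64), c(64, 64, 1))
  enc <- hybrid_encode(m, img)
  expect_equal(dim(enc$tokens), c(16, cfg$hidden_dim))   # (64/16)^2 tokens
  expect_length(enc$skips, 3)
  expect_equal(dim(enc$skips[[1]])[1:2], c(8, 8))        # 1/8 scale
  expect_equal(dim(enc$skips[[2]])[1:2], c(16, 16))      # 1/4
  expect_equal(dim(enc$skips[[3]])[1:2], c(32, 32))      # 1/2
  # token counts for the published input sizes
  expect_equal(cptseg:::n_tokens(cpt_config("cpt")), 196)
  expect_equal(cptseg:::n_tokens(cpt_config("cpt", image_size = 320)), 400)
})

test_that("decoder restores input resolution with n_classes channels", {
  cfg <- tiny_cpt_config()
  m <- build_model(cfg, seed = 2)
  img <- array(runif(64 * 64), c(64, 64, 1))
  enc <- hybrid_encode(m, img)
  logits <- decode_cup(m, enc$tokens, enc$skips)
  expect_equal(dim(logits), c(64, 64, 9))
  expect_error(decode_cup(m, enc$tokens[1:15, ], enc$skips), "square")
})

test_that("forward_segment yields normalized, deterministic probabilities", {
  m <- build_model(tiny_cpt_config(dropout = 0.2), seed = 3)
  img <- array(runif(64 * 64), c(64, 64, 1))
  p1 <- forward_segment(m, img)
  expect_lt(max(abs(apply(p1, c(1, 2), sum) - 1)), 1e-6)
  # evaluation mode ignores dropout and is bitwise reproducible
  expect_identical(p1, forward_segment(m, img))
  lab <- predict_slice(m, img)
  expect_true(all(lab >= 0 & lab <= 8))
  expect_error(forward_segment(m, array(0, c(32, 32, 1))), "expects")
})

test_that("every parameter tensor of every variant receives gradient", {
  img <- array(runif(64 * 64), c(64, 64, 1))
  set.seed(21)
  lab <- matrix(sample(0:8, 64 * 64, TRUE), 64, 64)
  for (cfg in list(tiny_cpt_config(),
                   cpt_config("parallel_vit", image_size = 64, depth = 1,
                              width_factor = 0.25, dropout = 0),
                   cpt_config("serial", image_size = 64, depth = 1,
                              width_factor = 0.25, dropout = 0),
                   tiny_cpt_config(branches = 3))) {
    m <- build_model(cfg, seed = 4)
    fw <- cptseg:::network_fwd(m, img, train = FALSE)
    ls <- cptseg:::seg_loss(fw$out, lab, 9, 0.5, 0.5)
    g <- cptseg:::network_bwd(m, ls$dlogits, fw$cache)
    fp <- flatten_params(m$params)
    fg <- flatten_params(g)
    expect_setequal(names(fg), names(fp))
    zero <- vapply(fg, function(x) all(x == 0), TRUE)
    expect_equal(sum(zero), 0,
                 info = paste(cfg$variant, cfg$branches, ":",
                              paste(names(fg)[zero], collapse = ", ")))
  }
})

test_that("network gradients match finite differences at probe points", {
  cfg <- cpt_config("cpt", image_size = 64, depth = 1, width_factor = 0.125,
                    dropout = 0)
  m <- build_model(cfg, seed = 8)
  img <- array(runif(64 * 64, 0.2, 0.8), c(64, 64, 1))
  set.seed(22)
  lab <- matrix(sample(0:8, 64 * 64, TRUE), 64, 64)
  lossfun <- function(mm) {
    fw <- cptseg:::network_fwd(mm, img, FALSE)
    cptseg:::seg_loss(fw$out, lab, 9, 0.5, 0.5)$loss
  }
  fw <- cptseg:::network_fwd(m, img, FALSE)
  ls <- cptseg:::seg_loss(fw$out, lab, 9, 0.5, 0.5)
  g <- cptseg:::network_bwd(m, ls$dlogits, fw$cache)
  probes <- list(c("embed", "pos"),
                 c("transformer", "1", "left", "wq", "W"),
                 c("transformer", "1", "right", "dd", "1", "v", "W"),
                 c("transformer", "1", "fuse", "ln_ql", "gain"),
                 c("dec", "head", "b"))
  eps <- 1e-5
  for (path in probes) {
    ga <- g
    for (k in path) ga <- ga[[if (grepl("^[0-9]+$", k)) as.integer(k) else k]]
    i <- 1L
    bump <- function(delta) {
      mm <- m
      ref <- paste0("mm$params", paste0(sprintf(
        "[[%s]]", vapply(path, function(k) {
          if (grepl("^[0-9]+$", k)) k else sprintf('"%s"', k)
        }, "")), collapse = ""))
      eval(parse(text = sprintf("%s[%d] <- %s[%d] + delta", ref, i, ref, i)))
      mm
    }
    num <- (lossfun(bump(eps)) - lossfun(bump(-eps))) / (2 * eps)
    expect_equal(ga[i], num, tolerance = 1e-3,
                 info = paste(path, collapse = "."))
  }
})

test_that("configurations round-trip through YAML", {
  cfg <- cpt_config("cpt", image_size = 64, depth = 3, branches = 2,
                    dd_layers = 2, mlp_layers = 1, width_factor = 0.25,
                    dropout = 0.05)
  path <- tempfile(fileext = ".yaml")
  write_cpt_config(cfg, path)
  back <- read_cpt_config(path)
  for (f in c("variant", "image_size", "depth", "branches", "dd_layers",
              "mlp_layers", "hidden_dim", "mlp_dim", "heads", "dropout",
              "bias", "width_factor")) {
    expect_equal(back[[f]], cfg[[f]], info = f)
  }
  unlink(path)
})
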