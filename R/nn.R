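# Minimal fully connected network machinery for the AC-GAN, written with
# plain matrix algebra so that per-participant gradients (needed for DP
# clipping) are available in closed form. For a dense layer the gradient of
# example i factorises as outer(input_i, delta_i), so its squared norm is
# |input_i|^2 * |delta_i|^2 and clipped gradient sums reduce to one matrix
# product with row-scaled deltas -- no per-example loop.

lrelu <- function(z, alpha = 0.2) ifelse(z > 0, z, alpha * z)
lreluGrad <- function(z, alpha = 0.2) ifelse(z > 0, 1, alpha)

heInit <- function(nin, nout) {
    matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

# Generator: (z, arm embedding) -> 128 -> 128 -> outDim, ReLU hidden, tanh
# output squashing into [-1, 1].
initGenerator <- function(latentDim, embedDim, hidden, outDim,
                          armLevels = c("standard", "intensive"),
                          visits = NULL, variables = NULL, ranges = NULL,
                          countVariables = "MEDS") {
    inDim <- latentDim + embedDim
    params <- list(
        Emb = matrix(stats::rnorm(2 * embedDim, sd = 1), 2, embedDim),
        W1 = heInit(inDim, hidden), b1 = rep(0, hidden),
        W2 = heInit(hidden, hidden), b2 = rep(0, hidden),
        W3 = matrix(stats::rnorm(hidden * outDim, sd = sqrt(1 / hidden)),
                    hidden, outDim),
        b3 = rep(0, outDim))
    new("GanModel", role = "generator", params = params,
        arch = list(latentDim = latentDim, embedDim = embedDim,
                    hidden = hidden, outDim = outDim, armLevels = armLevels,
                    visits = visits, variables = variables, ranges = ranges,
                    countVariables = countVariables,
                    activations = c("relu", "relu", "tanh")))
}

# Discriminator: x -> 128 -> 128 -> {source logit, arm logit}, leaky-ReLU
# hidden activations, sigmoid heads.
initDiscriminator <- function(inDim, hidden,
                              armLevels = c("standard", "intensive")) {
    params <- list(
        W1 = heInit(inDim, hidden), b1 = rep(0, hidden),
        W2 = heInit(hidden, hidden), b2 = rep(0, hidden),
        ws = stats::rnorm(hidden, sd = sqrt(1 / hidden)), bs = 0,
        wa = stats::rnorm(hidden, sd = sqrt(1 / hidden)), ba = 0)
    new("GanModel", role = "discriminator", params = params,
        arch = list(inDim = inDim, hidden = hidden, armLevels = armLevels,
                    activations = c("lrelu", "lrelu", "sigmoid")))
}

addRow <- function(m, b) sweep(m, 2, b, "+")

genForwardInternal <- function(model, z, armIdx) {
    p <- model@params
    X <- cbind(z, p$Emb[armIdx, , drop = FALSE])
    Z1 <- addRow(X %*% p$W1, p$b1); H1 <- pmax(Z1, 0)
    Z2 <- addRow(H1 %*% p$W2, p$b2); H2 <- pmax(Z2, 0)
    Y <- tanh(addRow(H2 %*% p$W3, p$b3))
    list(X = X, Z1 = Z1, H1 = H1, Z2 = Z2, H2 = H2, Y = Y)
}

discForwardInternal <- function(model, X) {
    p <- model@params
    X <- as.matrix(X)
    Z1 <- addRow(X %*% p$W1, p$b1); H1 <- lrelu(Z1)
    Z2 <- addRow(H1 %*% p$W2, p$b2); H2 <- lrelu(Z2)
    list(X = X, Z1 = Z1, H1 = H1, Z2 = Z2, H2 = H2,
         srcLogit = drop(H2 %*% p$ws) + p$bs,
         armLogit = drop(H2 %*% p$wa) + p$ba)
}

# Backward pass through the discriminator given per-example head
# derivatives dSrc = dL_i/dsrcLogit_i, dArm = dL_i/darmLogit_i.
discBackwardInternal <- function(model, fw, dSrc, dArm) {
    p <- model@params
    deltaH2 <- outer(dSrc, p$ws) + outer(dArm, p$wa)
    deltaZ2 <- deltaH2 * lreluGrad(fw$Z2)
    deltaH1 <- deltaZ2 %*% t(p$W2)
    deltaZ1 <- deltaH1 * lreluGrad(fw$Z1)
    deltaX <- deltaZ1 %*% t(p$W1)
    list(dSrc = dSrc, dArm = dArm, deltaZ2 = deltaZ2, deltaZ1 = deltaZ1,
         deltaX = deltaX)
}

# Squared 2-norm of each example's full discriminator gradient (all layers,
# weights and biases), from the factorised per-layer norms.
discPerExampleNormSq <- function(fw, bk) {
    h2sq <- rowSums(fw$H2^2)
    bk$dSrc^2 * (h2sq + 1) + bk$dArm^2 * (h2sq + 1) +
        rowSums(bk$deltaZ2^2) * (rowSums(fw$H1^2) + 1) +
        rowSums(bk$deltaZ1^2) * (rowSums(fw$X^2) + 1)
}

# Weighted gradient sum over examples: scale is a per-example weight vector
# (1/B for a mean step, the clip factors c_i for a DP step).
discGradients <- function(fw, bk, scale) {
    sS <- bk$dSrc * scale
    sA <- bk$dArm * scale
    dZ2 <- bk$deltaZ2 * scale
    dZ1 <- bk$deltaZ1 * scale
    list(W1 = crossprod(fw$X, dZ1), b1 = colSums(dZ1),
         W2 = crossprod(fw$H1, dZ2), b2 = colSums(dZ2),
         ws = drop(crossprod(fw$H2, sS)), bs = sum(sS),
         wa = drop(crossprod(fw$H2, sA)), ba = sum(sA))
}

applyGradients <- function(model, grads, lr) {
    for (nm in names(grads)) {
        model@params[[nm]] <- model@params[[nm]] - lr * grads[[nm]]
    }
    model
}

# Gradient of the generator loss given dY = dL/dY (B x outDim, already
# scaled by 1/B) from backpropagating through the discriminator.
genGradients <- function(model, fw, dY, armIdx) {
    p <- model@params
    deltaZ3 <- dY * (1 - fw$Y^2)
    deltaH2 <- deltaZ3 %*% t(p$W3)
    deltaZ2 <- deltaH2 * (fw$Z2 > 0)
    deltaH1 <- deltaZ2 %*% t(p$W2)
    deltaZ1 <- deltaH1 * (fw$Z1 > 0)
    deltaX <- deltaZ1 %*% t(p$W1)
    latentDim <- model@arch$latentDim
    deltaEmbRows <- deltaX[, latentDim + seq_len(model@arch$embedDim),
                           drop = FALSE]
    gEmb <- matrix(0, 2, model@arch$embedDim)
    for (a in 1:2) {
        rows <- armIdx == a
        if (any(rows)) gEmb[a, ] <- colSums(deltaEmbRows[rows, , drop = FALSE])
    }
    list(Emb = gEmb,
         W1 = crossprod(fw$X, deltaZ1), b1 = colSums(deltaZ1),
         W2 = crossprod(fw$H1, deltaZ2), b2 = colSums(deltaZ2),
         W3 = crossprod(fw$H2, deltaZ3), b3 = colSums(deltaZ3))
}

initAdam <- function(params) {
    list(m = lapply(params, function(x) x * 0),
         v = lapply(params, function(x) x * 0), t = 0)
}

# beta1 = 0.5: the usual GAN setting, damping momentum so the two players
# track each other's moves instead of overshooting.
adamStep <- function(model, grads, state, lr, beta1 = 0.5, beta2 = 0.999,
                     eps = 1e-8) {
    state$t <- state$t + 1
    for (nm in names(grads)) {
        state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
        state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
        mhat <- state$m[[nm]] / (1 - beta1^state$t)
        vhat <- state$v[[nm]] / (1 - beta2^state$t)
        model@params[[nm]] <- model@params[[nm]] -
            lr * mhat / (sqrt(vhat) + eps)
    }
    list(model = model, state = state)
}
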