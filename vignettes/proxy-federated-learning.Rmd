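---
title: "Proxy-based decentralized federated learning: models, privacy accounting, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proxy-based decentralized federated learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxyfl)
```

## The problem

Institutions in regulated domains (hospitals exchanging histopathology
models are the motivating case) want to train classifiers collaboratively
without centralizing data, without a coordinating server, and with a
quantitative privacy guarantee on everything that leaves their premises.
`proxyfl` simulates, on a single machine, the protocol that addresses all
three constraints at once: every client $k$ keeps a **private model**
$f_{\phi_k}$ that never leaves the client, and a **proxy model**
$h_{\theta_k}$ of a common architecture that is the sole interface to the
outside world. Proxies are trained with differentially private gradient
steps, so releasing them carries an explicit $(\epsilon, \delta)$
guarantee, and are exchanged peer-to-peer by PushSum gossip on a directed
time-varying graph.

## Training objectives

Within a round, each client alternates stochastic gradient steps between
its two models (deep mutual learning). With $\mathrm{CE}$ the
cross-entropy and $\mathrm{KL}$ the Kullback–Leibler divergence between
predictive distributions, the private model minimizes

$$\mathcal{L}_{\phi_k} = (1-\alpha)\,\mathcal{L}_{\mathrm{CE}}(f_{\phi_k})
  + \alpha\,\mathcal{L}_{\mathrm{KL}}(f_{\phi_k} \,\|\, h_{\theta_k}),$$

and the proxy minimizes the mirror image with weight $\beta$ and the KL
direction reversed, $\mathrm{KL}(h_{\theta_k} \| f_{\phi_k})$. Both
expectations are estimated on the same mini-batch in a step pair. The peer
model's predictions are treated as constants ("detached"): alternating
updates presuppose that no gradient flows through the peer, and
`mixed_per_example_grads()` implements exactly that. $\alpha, \beta \in
(0,1)$ balance task loss against mutual distillation; the package defaults
are $\alpha = \beta = 0.5$ (the benchmark setting), and probabilities are
floored at $10^{-12}$ inside logarithms — numerical safety that does not
measurably alter any loss at double precision.

## Differentially private proxy training

Only proxies spend privacy budget. A DP step (`dp_step()`) computes
per-example mixed gradients, clips each row to L2 norm $C$
($g \mapsto g / \max(1, \|g\|_2 / C)$, the standard per-example clipping
under which the sensitivity bound holds), sums the rows, adds Gaussian
noise $\mathcal{N}(0, \sigma^2 C^2 I)$, and divides by the realized batch
size. Mini-batches are Poisson-subsampled: each example participates
independently with probability $q$, the regime the subsampled-Gaussian
privacy analysis assumes. Accounting uses the sampling rate $q$; the
update divides by the realized batch size; empty draws are skipped with no
update and no receipt. DP-Adam feeds the privatized mean gradient into an
ordinary Adam update — post-processing preserves the guarantee, so the
moments need no extra noise. Private models never pass through this
pipeline; `dp_step()` refuses to run when DP is disabled, and every
privatized release emits exactly one accounting receipt.

## Privacy accounting

Each client tracks its own guarantee in the Rényi-DP framework. The
per-step Rényi divergence bound of the Poisson-subsampled Gaussian
mechanism is computed at a grid of orders:

* at integer orders, by the tight binomial-expansion bound
  $\tfrac{1}{\alpha-1}\log \sum_{k=0}^{\alpha} \binom{\alpha}{k}
  (1-q)^{\alpha-k} q^k e^{k(k-1)/2\sigma^2}$, evaluated in log space;
* at non-integer orders, by normalized numerical quadrature of the
  defining integral $\mathbb{E}_{z\sim\mathcal{N}(0,\sigma^2)}\big[((1-q) +
  q\,e^{(2z-1)/2\sigma^2})^\alpha\big]$, which is valid for any real
  $\alpha > 1$ and coincides with the binomial sum at integers — the two
  routes agree to about $10^{-15}$ and are cross-checked in the test
  suite. The log-integrand can peak near $z \approx \alpha$, far above
  zero, so it is normalized by its maximum over a bracketing grid before
  `integrate()` is called.

Bounds compose additively over steps and convert to $(\epsilon, \delta)$
by minimizing over orders. The default conversion is
$\epsilon = \mathrm{rdp} + \log(1 - 1/\alpha) - (\log\delta +
\log\alpha)/(\alpha - 1)$, the improved variant used by widely deployed
accountants; the classic $\mathrm{rdp} + \log(1/\delta)/(\alpha-1)$ is
available via `conversion = "classic"`. The improved variant is the
default because it is the one that reproduces the published per-client
guarantees this package's acceptance checks recompute — the classic
variant overshoots them by roughly 18%, far outside the 2% agreement the
improved conversion achieves. The order grid is
$\{1.1, 1.2, \ldots, 10.9\} \cup \{2, \ldots, 64\} \cup \{128, 256, 512,
1024, 2048, 4096\}$: dense where training-scale optima land (orders
9–17 for the histopathology-scale settings), with a sparse large-order
tail so that near-zero-RDP regimes (huge noise) are not floored by the
grid maximum. "Epoch-equivalent" training is $\lceil N/B \rceil$ steps
per epoch at $q = B/N$, so `epsilon_for_training(N, B, epochs, sigma,
delta)` reproduces a full run's guarantee from printed inputs only.
$\delta$ is caller-specified throughout; the histopathology-scale setting
uses $10^{-5}$.

```{r accountant}
epsilon_for_training(N = 2338, B = 32, epochs = 30, sigma = 1.4,
                     delta = 1e-5)
```

## Communication

`exponential_graph(t, K)` builds the round-$t$ permutation of the directed
exponential protocol: client $k$ sends to $(k + 2^{t \bmod m}) \bmod K$
with $m = \lfloor \log_2(K-1) \rfloor + 1$, so offsets cycle through
$1, 2, 4, \ldots$ and any client's information reaches all $K$ clients in
$\lceil \log_2 K \rceil$ rounds while each client sends and receives
exactly one proxy per round. Mixing matrices must be column-stochastic
(mass conservation); they need not be symmetric or constant over time.
`pushsum_mix()` applies $\Theta' = P\Theta$, $w' = Pw$ and `debias()`
divides $\theta_k / w_k$, which tracks the network average of the initial
proxies under repeated mixing.

Within a protocol round, communication is a one-shot
aggregate-and-replace: after mixing, each proxy is set to its de-biased
received aggregate and the PushSum weight is reset to 1 for the next
round. With the permutation protocol the weights are identically 1, so
this is exact; for general column-stochastic matrices it makes each round
a weighted aggregate rather than a long-run consensus, matching the
alternate-train-and-communicate structure (running gossip to convergence
between training rounds is precisely what the protocol avoids).
Communicate-only consensus is still available — and tested — through the
module surface (`pushsum_mix()` iterated without reset).

Initialization follows the standard federated convention, declared here
because averaging is meaningless across independently initialized
networks: all shared-architecture models (proxies, and the single models
of the baselines) start from one common seed, while private models use
per-client seeds. Optimizer state persists across rounds. Clients whose
prespecified budget $\epsilon$ is reached drop out; subsequent rounds
restrict the graph to the remaining clients.

## Protocols

`run_protocol()` drives seven methods on the same substrate: the
proxy-sharing protocol itself (`proxyfl`), `fml` (mutual learning with
central uniform averaging of proxies), `fedavg` (central parameter
averaging), `avgpush` (decentralized averaging via one PushSum exchange
per round), `cwt` (cyclic model passing), `regular` (isolated local
training), and `joint` (one model on the pooled data). Single-model
methods train their model with DP; the two-model methods apply DP to
proxies only, which is the point: the private model, used for inference,
is never noised. FML's central aggregation uses a uniform (unweighted)
mean over clients.

## The synthetic task and what it does (not) show

`make_synthetic()` draws isotropic Gaussian class blobs: class means are
scaled so the typical pairwise mean distance is about $\sqrt{2}\,
\times$ `class_separation` independent of dimension, with within-class
noise `noise_sd`. The two partitioners reproduce the non-IID
constructions of the benchmark settings: `partition_skewed()` gives each
client a randomly assigned major class holding
$\lfloor p_\mathrm{major} \cdot n \rfloor$ of its examples (remainder
IID over the other classes; $p_\mathrm{major} = 1/\text{n\_classes}$ is
the IID setting), and `partition_dirichlet()` allocates each class across
clients with Dirichlet-distributed proportions (concentration 0.5 in the
endoscopy-style setting), realized by largest-remainder rounding so class
totals are conserved exactly. The shared test set is an IID draw from the
same pooled distribution.

Gaussian blobs are linearly separable in a way image data is not; passing
the protocol-ordering checks here demonstrates the mechanics of
collaboration under label skew — that proxy exchange transfers
information a skewed client lacks — not the absolute accuracies of
full-scale image experiments, which require the real datasets and
GPU-scale models and are deliberately out of scope.

## Scaled-down study sizes

The protocol-comparison checks run at: 10 classes in 16 dimensions,
separation 3, noise 1, 8 clients with 200 examples each at
$p_\mathrm{major} = 0.8$, batch 32, MLPs with one hidden layer of 32,
Adam at learning rate 0.005, $C = 1$, $\sigma = 1$, 15 rounds, 5 seeds —
sizes at which the qualitative ordering (pooled training above
collaborating private models above isolated training) is stable with wide
margins. The full-scale defaults of `protocol_config()` (learning rate
0.001, batch 250) mirror the benchmark settings instead.

## Degenerate inputs and numerical choices

Per-example gradients are computed by exact per-example backpropagation
(vectorized over the batch for MLPs via row-wise outer products; per
example with im2col for CNNs), never approximated — exactness is what the
sensitivity argument needs, and the suite verifies rows against central
finite differences. Clipping at exactly $\|g\| = C$ is a no-op
(`max(1, ...)`). $\sigma = 0$ is accepted for oracle tests only.
Empty Poisson draws are skipped. Default architectures contain no
normalization layers: batch-coupled statistics would break per-example
sensitivity. Ties in argmax evaluation resolve to the first class.
A fresh accountant converts to a small positive $\epsilon$ (the
conversion's floor at the largest grid order) rather than exactly zero;
reports at round 0 show that floor.

## Known limitations

Single-process simulation only (the send/receive contract matches what a
message-passing deployment would use, but no transport layer is
provided); no stragglers, asynchrony, or adversarial clients; no
per-layer adaptive clipping or secure aggregation; group-level privacy
(several datapoints per patient) is not modeled — guarantees are stated
per datapoint. CNN per-example gradients loop over examples and are
intended for small fixtures, not image-scale training.
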