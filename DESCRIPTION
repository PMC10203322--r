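Package: proxyfl
Title: Decentralized Federated Learning by Proxy Model Sharing with
    Differential Privacy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A seedable, single-machine multi-client simulator for
    proxy-based decentralized federated learning. Each simulated client
    trains a private classifier together with a differentially private
    proxy classifier by deep mutual learning, and exchanges only the proxy
    via PushSum gossip on directed exponential graphs. Includes per-example
    gradient computation for small MLP and CNN classifiers, DP-SGD with
    per-example clipping and Gaussian noise, a Renyi differential privacy
    accountant for the Poisson-subsampled Gaussian mechanism with
    conversion to (epsilon, delta) guarantees, six comparison protocols
    (FedAvg, AvgPush, CWT, FML, Regular, Joint), non-IID label-skew and
    Dirichlet data partitioners, and a reproducible experiment driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
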