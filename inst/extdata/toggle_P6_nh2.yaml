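# Symmetric toggle switch, strong-promoter stress test: P = 6 gene copies,
# Hill coefficient 2. Region: the copy-number convention around the stable
# state (S1, S2) = (30, 0).
model:
  species: [S1, S2]
  params: {alpha: 0.05, beta: 0.01, P: 6.0, nh: 2.0, K: 10.0}
  reactions:
    - {type: hill-repression, delta: [1, 0], vmax: alpha*P, repressor: S2,
       K: K, nh: nh, label: S1 production}
    - {type: hill-repression, delta: [0, 1], vmax: alpha*P, repressor: S1,
       K: K, nh: nh, label: S2 production}
    - {type: mass-action, delta: [-1, 0], k: beta, species: S1,
       label: S1 degradation}
    - {type: mass-action, delta: [0, -1], k: beta, species: S2,
       label: S2 degradation}
region:
  box:
    S1: [alpha/(3*beta)*P, 2*alpha/beta*P]
    S2: [0, P]
initial:
  point: {S1: 30, S2: 0}
times: [21600, 43200, 86400]
eps: 1.0e-6
max_loops: 100000
qsd_method: restriction
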