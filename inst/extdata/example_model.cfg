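# Moderated mediation with a composite mediator: a latent predictor X,
# a three-component composite M, and a latent outcome Y.
latent: X
  indicators: x1 x2 x3
composite: M
  components: m1 m2 m3
latent: Y
  indicators: y1 y2 y3
structural:
  predictor: X
  mediator: M
  outcome: Y
  interaction: X:M
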