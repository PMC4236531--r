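# Self-selected-speed overground gait, one stride (heel strike to heel
# strike).  Angles in radians (hip/knee extension +, ankle plantarflexion +),
# moments in Nm/kg of the cycle fraction.
activity: gait
cyclic: true
duration: 1.1
sampling_rate: 100
noise_sd: 0.0
angles:
  hip:
    mean: -0.17
    harmonics:
      - {order: 1, amp: 0.35, phase: 3.14159}
      - {order: 2, amp: 0.04, phase: 1.0}
  knee:
    mean: -0.55
    harmonics:
      - {order: 1, amp: 0.45, phase: 4.084}
  ankle:
    mean: 0.05
    harmonics:
      - {order: 1, amp: 0.22, phase: 3.83}
      - {order: 2, amp: 0.14, phase: 0.95}
moments:
  ankle:
    - {center: 0.45, width: 0.10, amp: 1.40}
    - {center: 0.06, width: 0.04, amp: -0.11}
  knee:
    - {center: 0.15, width: 0.07, amp: 0.60}
    - {center: 0.45, width: 0.08, amp: -0.42}
  hip:
    - {center: 0.08, width: 0.08, amp: 0.80}
    - {center: 0.55, width: 0.10, amp: -0.63}
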