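# Sit-to-stand from a chair at knee height, no hand support.  Logistic
# transitions from the seated to the standing posture; knee and hip extensor
# moments peak around seat-off (mid-movement).
activity: sit_to_stand
cyclic: false
duration: 2.4
sampling_rate: 100
noise_sd: 0.0
angles:
  hip:   {start: -1.50, end: -0.05, center: 1.2, width: 0.30}
  knee:  {start: -1.50, end: -0.12, center: 1.2, width: 0.30}
  ankle: {start: -0.15, end:  0.05, center: 1.2, width: 0.30}
moments:
  knee:
    - {center: 0.50, width: 0.10, amp: 0.90}
  hip:
    - {center: 0.48, width: 0.10, amp: 0.78}
  ankle:
    - {center: 0.60, width: 0.12, amp: 0.40}
    - {center: 0.30, width: 0.08, amp: -0.10}
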