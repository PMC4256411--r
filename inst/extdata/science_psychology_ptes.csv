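year,authors,short_title,p_tes
2006,Dijksterhuis et al.,Deliberation-Without-Attention Effect,0.051
2006,Vohs et al.,Psychological Consequences of Money,0.002
2006,Zhong & Lijenquist,Washing Away Your Sins,0.095
2007,Wood et al.,Perception of Goal-Directed Action in Primates,0.031
2008,Whitson & Galinsky,Lacking Control Increases Illusory Pattern Perception,0.008
2009,Mehta & Zhu,Effect of Color on Cognitive Performance,0.002
2009,Paukner et al.,Monkeys Display Affiliation Toward Imitators,0.037
2009,Weisbuch et al.,Race Bias via Televised Nonverbal Behavior,0.027
2010,Ackerman et al.,Incidental Haptic Sensations Influence Decisions,0.017
2010,Bahrami et al.,Optimally Interacting Minds,0.332
2010,Kovács et al.,Susceptibility to Others' Beliefs in Infants and Adults,0.021
2010,Morewedge et al.,Imagined Consumption Reduces Actual Consumption,0.012
2011,Halperine et al.,Promoting the Middle East Peace Process,0.210
2011,Ramirez & Beilock,Writing About Worries Boosts Exam Performance,0.059
2011,Stapel & Lindenberg,Disordered Contexts Promote Stereotyping,0.075
2012,Gervais & Norenzayan,Analytic Thinking Promotes Religious Disbelief,0.051
2012,Seeley et al.,Stop Signals Provide Inhibition in Honeybee Swarms,0.957
2012,Shah et al.,Some Consequences of Having Too Little,0.091
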