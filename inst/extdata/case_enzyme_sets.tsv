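case	metabolite	enzymes
BPA	BPA_I_1	1A1,1A2,1B1,3A4
BPA	BPA_I_2	1A2,2D6,2E1
BPA	BPA_I_3	2E1
PCB3	PCB_I_1	1A1,1B1,1A2,2A6,2B6,2C9,2C19,2E1,3A4
PCB3	PCB_I_2	1B1,2B6,2C8,2C9,2C18,2C19,2D6,2E1,3A4,3A5
PCB3	PCB_I_3	1A1,1B1,2C8,2C9,2E1,3A4
PCB3	PCB_I_4	2B6,3A4
PCB3	PCB_I_5	3A4
PCB3	PCB_I_6	2E1
PCB3	PCB_I_7	2E1
PCB3	PCB_I_8	2C9,2C19
PCB3	PCB_I_9	1A2
PCB3	PCB_I_10	2D6
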