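icd9,site_group
140,Head/neck
141,Head/neck
142,Head/neck
143,Head/neck
144,Head/neck
146,Head/neck
147,Head/neck
148,Head/neck
149,Head/neck
160,Head/neck
161,Head/neck
150,Other GI
151,Other GI
152,Colon/intestines
153,Colon/intestines
154,Rectum
155,Liver
156,Other GI
157,Other GI
158,Other GI
159,Other GI
162,Lung
163,Lung
164,Lung
165,Lung
170,Bone
171,Soft tissue
172,Melanoma
173,Skin
174,Breast
175,Breast
179,Other GYN
180,Other GYN
181,Other GYN
182,Other GYN
183,Ovary
184,Other GYN
185,Prostate/Testis/Penis
186,Prostate/Testis/Penis
187,Prostate/Testis/Penis
188,Bladder
189,Kidney
190,CNS
191,CNS
192,CNS
193,Thyroid/Endo
194,Thyroid/Endo
195,Unspecified group 1
196,Unspecified group 1
197,Unspecified group 2
198,Unspecified group 2
199,Unspecified group 2
200,Lymphoid/leukemia
201,Hodgkin's disease
202,Lymphoid/leukemia
203,Myeloma
204,Lymphoid/leukemia
205,Lymphoid/leukemia
206,Lymphoid/leukemia
207,Lymphoid/leukemia
208,Lymphoid/leukemia
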