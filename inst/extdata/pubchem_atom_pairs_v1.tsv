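bit	elem1	elem2
263	Li	H
264	Li	Li
265	B	H
266	B	B
267	B	C
268	B	N
269	B	O
270	B	F
271	B	Si
272	B	P
273	B	S
274	B	Cl
275	B	Br
276	C	H
277	C	C
278	C	N
279	C	O
280	C	F
281	C	Na
282	C	Mg
283	C	Al
284	C	Si
285	C	P
286	C	S
287	C	Cl
288	C	As
289	C	Se
290	C	Br
291	C	I
292	N	H
293	N	N
294	N	O
295	N	F
296	N	Si
297	N	P
298	N	S
299	N	Cl
300	N	Br
301	O	H
302	O	O
303	O	Mg
304	O	Na
305	O	Al
306	O	Si
307	O	P
308	O	K
309	F	P
310	F	S
311	Si	H
312	Si	Si
313	Si	Cl
314	P	H
315	P	P
316	P	S
317	S	H
318	S	S
319	S	Cl
320	Cl	H
321	Br	H
322	I	H
323	Se	H
324	Se	Se
325	As	H
326	As	As
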