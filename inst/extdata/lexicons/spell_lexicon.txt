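able
about
advice
after
afternoon
again
aggravating
aggressive
alcohol
almost
along
already
also
always
another
anyone
anything
anytime
appointment
around
back
because
been
before
best
better
between
biopsy
blood
bone
brain
breast
came
cancer
care
change
changed
checkup
chemo
chemotherapy
clean
clear
clearly
clinic
come
completed
counts
curls
daughter
days
denosumab
details
diagnosed
doctor
doctors
does
dose
double
during
earlier
early
email
energy
esophageal
even
evening
every
everyone
example
explained
factors
family
feel
feeling
fine
finished
first
five
flash
found
friend
friends
from
good
grade
great
guide
hair
happy
hard
have
haven
having
hear
heard
hello
help
helped
here
home
hope
hoping
hospital
http
hugs
infusion
inoperable
internal
just
keep
kind
know
last
late
latest
left
less
little
live
long
looked
looking
lord
loss
love
lymph
made
major
many
mastectomy
maybe
melanoma
members
metastasis
might
mild
mind
moment
month
months
more
morning
most
mother
much
must
need
needle
negative
nerve
never
news
next
nice
night
node
nurse
nurses
office
okay
oncologist
online
only
onto
other
over
pain
pancreatic
peace
plan
port
positive
pray
prayers
primary
probably
prostate
radiation
rather
read
ready
really
recommended
rest
rested
results
round
rounds
said
scan
scans
sending
seven
several
showed
sick
side
sign
signature
signing
since
sister
skip
sleep
slept
slow
smoking
some
someone
something
soon
sore
spread
spring
stage
started
starts
stay
stereotactic
steroids
still
strength
strong
support
supportive
sure
surgeon
surgery
take
taking
talk
tamoxifen
team
tell
test
tests
than
thank
thanks
that
their
them
then
there
these
they
things
think
this
those
though
three
time
times
tired
today
together
told
tomorrow
took
treatment
treatments
triple
tumor
type
under
until
upbeat
update
very
visit
visited
wait
waiting
walk
want
warm
week
weeks
well
went
were
what
when
where
which
while
will
wish
wishes
wishing
with
without
woke
wonderful
words
work
worried
would
www
year
years
yesterday
your
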