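# Common English words excluded from surface-name matching.
# One word per line; lines starting with '#' are comments.
the
and
for
are
but
not
you
all
any
can
had
her
was
one
our
out
day
get
has
him
his
how
man
new
now
old
see
two
way
who
boy
did
its
let
put
say
she
too
use
about
after
again
against
also
among
because
been
before
being
below
between
both
could
does
doing
down
during
each
even
every
first
from
further
have
having
here
himself
herself
itself
into
just
like
made
make
many
more
most
much
must
never
only
other
over
same
should
since
some
still
such
than
that
their
them
then
there
these
they
this
those
through
thus
under
until
upon
very
were
what
when
where
which
while
with
within
without
would
your
yours
above
across
along
already
although
always
another
anything
around
away
back
become
becomes
began
begin
behind
better
came
cannot
certain
come
comes
different
done
either
else
enough
ever
few
find
found
give
given
gives
goes
going
gone
good
great
group
high
however
important
itself
keep
kind
know
known
large
last
later
least
less
life
little
long
look
lower
main
may
mean
means
might
more
moreover
near
need
needs
next
none
nothing
number
often
once
open
order
others
otherwise
own
part
past
perhaps
place
point
possible
present
probably
provide
provides
quite
rather
really
result
results
right
said
second
seem
seems
seen
several
show
shown
shows
side
small
something
sometimes
soon
state
take
taken
tell
term
terms
things
think
three
time
times
together
took
toward
turn
turned
used
using
usually
value
various
want
well
went
whether
whole
why
will
work
works
year
years
yet
young
act
age
aid
air
arm
art
ask
bad
bar
base
bed
big
bit
body
book
call
car
care
case
cell
cent
city
class
clear
close
cold
color
cost
course
cut
dark
data
deep
develop
development
direct
early
earth
east
easy
effect
end
face
fact
fall
family
far
fast
feel
field
figure
final
fine
fire
food
form
free
full
gave
general
got
grow
growth
half
hand
hard
head
hear
heard
heart
heat
help
home
hope
hot
hour
house
idea
increase
interest
job
land
late
lead
learn
learned
learning
left
level
light
line
list
live
local
love
low
map
mark
matter
memory
men
mind
miss
model
moment
money
month
morning
move
name
nature
night
north
note
object
office
once
paper
pass
pay
people
period
person
plan
play
power
press
process
produce
product
public
question
read
real
reason
red
report
rest
rise
road
room
rule
run
school
sea
sense
set
sharp
ship
short
signal
simple
sit
size
sleep
sound
south
space
speak
special
stand
star
start
stay
step
stop
story
strong
study
subject
sun
support
sure
surface
system
table
talk
test
thing
thought
total
touch
town
transport
tree
true
try
type
unit
voice
walk
war
watch
water
week
west
white
wide
wind
word
world
write
written
wrong
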